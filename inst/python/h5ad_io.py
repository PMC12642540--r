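"""CSV-triplet <-> h5ad bridge.

Usage:
    python h5ad_io.py export IN.h5ad OUT_DIR   # h5ad -> counts/coords/attrs CSVs
    python h5ad_io.py import IN_DIR OUT.h5ad   # CSVs -> h5ad
"""
import sys
import os

import numpy as np
import pandas as pd
import anndata as ad


def densify(x):
    return np.asarray(x.todense()) if hasattr(x, "todense") else np.asarray(x)


def do_export(h5ad_path, out_dir):
    a = ad.read_h5ad(h5ad_path)
    counts = a.layers["counts"] if "counts" in a.layers else a.X
    counts = densify(counts)
    if "spatial" not in a.obsm:
        raise SystemExit("h5ad file lacks obsm['spatial'] coordinates")
    coords = np.asarray(a.obsm["spatial"], dtype=float)
    ids = a.obs_names.astype(str)
    cdf = pd.DataFrame(counts, columns=a.var_names.astype(str))
    cdf.insert(0, "spot_id", ids.values)
    cdf.to_csv(os.path.join(out_dir, "counts.csv"), index=False)
    axes = ["x", "y", "z"][: coords.shape[1]]
    codf = pd.DataFrame(coords, columns=axes)
    codf.insert(0, "spot_id", ids.values)
    codf.to_csv(os.path.join(out_dir, "coords.csv"), index=False)
    adf = pd.DataFrame({"spot_id": ids.values})
    for col in a.obs.columns:
        adf[col] = np.asarray(a.obs[col].astype(str) if a.obs[col].dtype.name
                              in ("category", "object", "bool") else a.obs[col])
    if "perturbation" not in adf.columns:
        raise SystemExit("h5ad obs lacks a 'perturbation' column")
    adf.to_csv(os.path.join(out_dir, "attrs.csv"), index=False)


def do_import(in_dir, h5ad_path):
    cdf = pd.read_csv(os.path.join(in_dir, "counts.csv"))
    ids = cdf["spot_id"].astype(str).values
    counts = cdf.drop(columns=["spot_id"]).to_numpy(dtype=float)
    genes = [c for c in cdf.columns if c != "spot_id"]
    codf = pd.read_csv(os.path.join(in_dir, "coords.csv"))
    coords = codf.drop(columns=["spot_id"]).to_numpy(dtype=float)
    adf = pd.read_csv(os.path.join(in_dir, "attrs.csv"))
    a = ad.AnnData(X=counts)
    a.obs_names = ids
    a.var_names = genes
    a.obsm["spatial"] = coords
    for col in adf.columns:
        if col == "spot_id":
            continue
        v = adf[col]
        a.obs[col] = (pd.Categorical(v.astype(str).to_numpy())
                      if v.dtype == object else v.to_numpy())
    a.write_h5ad(h5ad_path)


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in ("export", "import"):
        raise SystemExit(__doc__)
    if sys.argv[1] == "export":
        do_export(sys.argv[2], sys.argv[3])
    else:
        do_import(sys.argv[2], sys.argv[3])
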