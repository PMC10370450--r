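"""Dump an h5ad embedding + label column to TSV for the R reader.

Usage: python read_h5ad.py <file.h5ad> <latent_key> <label_key|''> <out.tsv>

Reads obsm/<latent_key> and obs/<label_key> (plain, categorical-group or
codes+categories encodings) with h5py only; the expression matrix is
ignored.
"""
import sys

import h5py
import numpy as np


def _decode(arr):
    out = []
    for v in np.asarray(arr):
        if isinstance(v, bytes):
            v = v.decode("utf-8")
        out.append(str(v))
    return out


def _read_obs_column(f, key):
    obs = f["obs"]
    if key not in obs:
        raise KeyError("obs column '%s' not found" % key)
    item = obs[key]
    if isinstance(item, h5py.Group):  # anndata categorical encoding
        cats = _decode(item["categories"][...])
        codes = np.asarray(item["codes"][...], dtype=int)
        return [cats[c] if c >= 0 else "" for c in codes]
    return _decode(item[...])


def main(path, latent_key, label_key, out):
    with h5py.File(path, "r") as f:
        if "obsm" not in f or latent_key not in f["obsm"]:
            raise KeyError("obsm slot '%s' not found" % latent_key)
        X = np.asarray(f["obsm"][latent_key][...], dtype=float)
        obs = f["obs"]
        index_col = obs.attrs.get("_index", "index")
        if isinstance(index_col, bytes):
            index_col = index_col.decode("utf-8")
        if index_col in obs:
            ids = _read_obs_column(f, index_col)
        else:
            ids = ["cell_%d" % i for i in range(X.shape[0])]
        labels = _read_obs_column(f, label_key) if label_key else None

    with open(out, "w") as fh:
        cols = ["cell_id"] + ["dim_%d" % (j + 1) for j in range(X.shape[1])]
        if labels is not None:
            cols.append("label")
        fh.write("\t".join(cols) + "\n")
        for i in range(X.shape[0]):
            row = [ids[i]] + ["%.17g" % v for v in X[i]]
            if labels is not None:
                row.append(labels[i])
            fh.write("\t".join(row) + "\n")


if __name__ == "__main__":
    if len(sys.argv) != 5:
        sys.stderr.write(__doc__)
        sys.exit(2)
    try:
        main(sys.argv[1], sys.argv[2], sys.argv[3], sys.argv[4])
    except Exception as exc:  # surfaced as an R error message
        sys.stderr.write("read_h5ad: %s\n" % exc)
        sys.exit(1)
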