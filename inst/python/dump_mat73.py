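"""Dump numeric datasets of an HDF5-backed (v7.3) MAT-file for R.

Each top-level numeric dataset is written as little-endian float64 in
column-major (MATLAB) order, plus a manifest.json listing names, dims and
file names. Usage: python dump_mat73.py <file.mat> <outdir>
"""
import json
import sys

import h5py
import numpy as np


def main(path, outdir):
    entries = []
    with h5py.File(path, "r") as f:
        for i, name in enumerate(f.keys()):
            node = f[name]
            if not isinstance(node, h5py.Dataset):
                continue
            if node.dtype.kind not in "fiu":
                continue
            # HDF5 stores MATLAB arrays transposed; .T restores MATLAB dims
            arr = np.asarray(node[()]).T.astype("<f8")
            fname = "var%d.bin" % i
            with open("%s/%s" % (outdir, fname), "wb") as out:
                out.write(arr.flatten(order="F").tobytes())
            entries.append({"name": name, "dims": list(arr.shape),
                            "file": fname})
    with open("%s/manifest.json" % outdir, "w") as out:
        json.dump(entries, out)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
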