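"""Convert a Kay-format MAT file (betas/roi/roilabels) to JSON.

Usage: python mat_to_json.py input.mat output.json

Handles both legacy (scipy.io) and v7.3 (HDF5, via h5py) containers. The
betas array is emitted with dimensions voxels x stimuli x bootstraps.
"""
import json
import sys


def _squeeze_strings(x):
    out = []
    for item in x:
        while hasattr(item, "__len__") and not isinstance(item, str) and len(item) == 1:
            item = item[0]
        out.append(str(item))
    return out


def load_legacy(path):
    from scipy.io import loadmat

    m = loadmat(path, squeeze_me=False)
    betas = m["betas"]
    roi = m["roi"].ravel().tolist()
    roilabels = _squeeze_strings(m["roilabels"].ravel().tolist())
    return betas, roi, roilabels


def load_v73(path):
    import h5py
    import numpy as np

    with h5py.File(path, "r") as f:
        betas = np.array(f["betas"]).T  # MATLAB order -> voxels first
        roi = np.array(f["roi"]).ravel().tolist()
        labels = []
        for ref in np.array(f["roilabels"]).ravel():
            labels.append("".join(chr(c) for c in np.array(f[ref]).ravel()))
        return betas, roi, labels


def main(inp, outp):
    try:
        betas, roi, roilabels = load_legacy(inp)
    except NotImplementedError:
        betas, roi, roilabels = load_v73(inp)
    payload = {
        "betas": betas.tolist(),
        "roi": [int(r) for r in roi],
        "roilabels": roilabels,
        "dim": list(betas.shape),
    }
    with open(outp, "w") as fh:
        json.dump(payload, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
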