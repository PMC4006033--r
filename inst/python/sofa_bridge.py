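#!/usr/bin/env python
"""Minimal SOFA (SimpleFreeFieldHRIR) <-> JSON bridge.

SOFA files are netCDF-4, i.e. HDF5; this bridge reads/writes the small
subset of the convention needed here (Data.IR, Data.SamplingRate,
SourcePosition) using h5py, exchanging payloads as JSON on stdin/stdout.

Usage:
  python sofa_bridge.py read  <file.sofa>          -> JSON on stdout
  python sofa_bridge.py write <file.sofa> < JSON
"""
import json
import sys

import h5py
import numpy as np


def read_sofa(path):
    with h5py.File(path, "r") as f:
        conv = f.attrs.get("SOFAConventions", b"")
        if isinstance(conv, bytes):
            conv = conv.decode("utf-8", "replace")
        if "SimpleFreeFieldHRIR" not in str(conv):
            raise ValueError("not a SimpleFreeFieldHRIR SOFA file: %r" % conv)
        if "SourcePosition" not in f or "Data.IR" not in f:
            raise ValueError("missing SourcePosition or Data.IR")
        ir = np.asarray(f["Data.IR"])            # M x R x N
        sp = np.asarray(f["SourcePosition"])     # M x 3 (az, el, r)
        fs = float(np.asarray(f["Data.SamplingRate"]).ravel()[0])
    return {
        "sampling_rate": fs,
        "source_position": sp.tolist(),
        "ir": ir.tolist(),
    }


def write_sofa(path, payload):
    ir = np.asarray(payload["ir"], dtype="f8")   # M x R x N
    sp = np.asarray(payload["source_position"], dtype="f8")
    fs = float(payload["sampling_rate"])
    m, r, n = ir.shape
    with h5py.File(path, "w") as f:
        f.attrs["Conventions"] = "SOFA"
        f.attrs["SOFAConventions"] = "SimpleFreeFieldHRIR"
        f.attrs["SOFAConventionsVersion"] = "1.0"
        f.attrs["DataType"] = "FIR"
        f.create_dataset("Data.IR", data=ir)
        f.create_dataset("Data.SamplingRate", data=np.array([fs]))
        f["Data.SamplingRate"].attrs["Units"] = "hertz"
        f.create_dataset("Data.Delay", data=np.zeros((1, r)))
        f.create_dataset("SourcePosition", data=sp)
        f["SourcePosition"].attrs["Type"] = "spherical"
        f["SourcePosition"].attrs["Units"] = "degree, degree, metre"
        f.create_dataset("ListenerPosition", data=np.zeros((1, 3)))
        f.create_dataset(
            "ReceiverPosition",
            data=np.array([[0.0, 0.09, 0.0], [0.0, -0.09, 0.0]])[:r],
        )
        f.create_dataset("EmitterPosition", data=np.zeros((1, 3)))


def main(argv):
    if len(argv) < 3:
        sys.stderr.write(__doc__)
        return 2
    cmd, path = argv[1], argv[2]
    if cmd == "read":
        json.dump(read_sofa(path), sys.stdout)
    elif cmd == "write":
        write_sofa(path, json.load(sys.stdin))
    else:
        sys.stderr.write("unknown command: %s\n" % cmd)
        return 2
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
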