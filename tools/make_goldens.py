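#!/usr/bin/env python
"""Independent-oracle generator for the golden trajectory fixtures.

A deliberately plain two-column recursion (population, carrying capacity),
written before and independently of the package's simulator, used to freeze
expected values for the regression tests. Regenerates bit-identically:

    python tools/make_goldens.py
"""
import math
import os

HERE = os.path.dirname(os.path.abspath(__file__))
OUT = os.path.join(HERE, "..", "tests", "testthat")


def recursion(law, P0, K0, r, L, a, b, t0, t_end):
    rows = []
    P, K = P0, K0
    for t in range(t0, t_end + 1):
        rows.append((t, P, K))
        dP = r * P * (K - P)
        if law == "oc":
            dK = (L / P) * dP
        elif law == "cc_m":
            dK = (L / P - a * (1e6) ** (1.0 - b) * P ** b) * dP
        else:
            raise ValueError(law)
        P, K = P + dP, K + dK
        if not (P > 0 and K > 0 and math.isfinite(P) and math.isfinite(K)):
            break
    return rows


def write(path, cfg, rows, stride=1):
    with open(path, "w") as fh:
        for k, v in cfg.items():
            fh.write("# %s=%s\n" % (k, v))
        fh.write("year,P,K\n")
        for i, (t, P, K) in enumerate(rows):
            if i % stride == 0 or i == len(rows) - 1:
                fh.write("%d,%.17g,%.17g\n" % (t, P, K))


cfg = dict(law="oc", P0=2.25e8, K0=2.5e8, r=1e-13, L=5e9, a=0, b=0,
           t0=1, t_end=11)
write(os.path.join(OUT, "golden_oc_10step.csv"), cfg,
      recursion("oc", 2.25e8, 2.5e8, 1e-13, 5e9, 0, 0, 1, 11))

cfg = dict(law="oc", P0=2.25e8, K0=2.3e8, r=1.5e-13, L=3.9684e10, a=0, b=0,
           t0=1, t_end=2500)
write(os.path.join(OUT, "golden_oc_full.csv"), cfg,
      recursion("oc", 2.25e8, 2.3e8, 1.5e-13, 3.9684e10, 0, 0, 1, 2500),
      stride=10)

cfg = dict(law="cc_m", P0=2.25e8, K0=2.3e8, r=1.5e-13, L=3.9684e10, a=5e-14,
           b=2.1, t0=1, t_end=2500)
write(os.path.join(OUT, "golden_cc_full.csv"), cfg,
      recursion("cc_m", 2.25e8, 2.3e8, 1.5e-13, 3.9684e10, 5e-14, 2.1, 1,
                2500),
      stride=10)

print("wrote goldens to", OUT)
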