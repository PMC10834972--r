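"""Linear / mixed-integer programming backend (HiGHS via scipy.optimize).

Reads a JSON problem description from argv[1] and writes a JSON result to
argv[2].  Two problem kinds are supported:

  {"kind": "milp", "c": [...], "constraints": {"row": [...], "col": [...],
   "val": [...], "lb": [...], "ub": [...], "nrow": int},
   "bounds_lb": [...], "bounds_ub": [...], "integrality": [...],
   "time_limit": float|null, "mip_rel_gap": float}

  {"kind": "lp_batch", "problems": [ ... one milp-style dict each,
   without integrality ... ]}

Indices are 0-based.  Infinities are encoded as the strings "inf"/"-inf".
"""

import json
import sys

import numpy as np
from scipy import sparse
from scipy.optimize import Bounds, LinearConstraint, linprog, milp


def _num(x):
    if x == "inf":
        return np.inf
    if x == "-inf":
        return -np.inf
    return float(x)


def _arr(xs):
    return np.array([_num(x) for x in xs], dtype=float)


def _matrix(spec, ncol):
    nrow = int(spec["nrow"])
    mat = sparse.csc_matrix(
        (np.asarray(spec["val"], dtype=float),
         (np.asarray(spec["row"], dtype=int),
          np.asarray(spec["col"], dtype=int))),
        shape=(nrow, ncol),
    )
    return mat, _arr(spec["lb"]), _arr(spec["ub"])


def solve_milp(prob):
    c = np.asarray(prob["c"], dtype=float)
    mat, lb, ub = _matrix(prob["constraints"], len(c))
    res = milp(
        c,
        constraints=LinearConstraint(mat, lb, ub),
        integrality=np.asarray(prob["integrality"], dtype=int),
        bounds=Bounds(_arr(prob["bounds_lb"]), _arr(prob["bounds_ub"])),
        options={
            k: v
            for k, v in {
                "time_limit": prob.get("time_limit"),
                "mip_rel_gap": prob.get("mip_rel_gap"),
                "presolve": True,
            }.items()
            if v is not None
        },
    )
    out = {"status": int(res.status), "message": str(res.message)}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["fun"] = float(res.fun)
        out["mip_dual_bound"] = float(getattr(res, "mip_dual_bound", res.fun))
        out["mip_gap"] = float(getattr(res, "mip_gap", 0.0))
    return out


def solve_lp(prob):
    c = np.asarray(prob["c"], dtype=float)
    mat, lb, ub = _matrix(prob["constraints"], len(c))
    # split two-sided rows into A_ub form for linprog
    a_ub = sparse.vstack([mat, -mat]).tocsc()
    b_ub = np.concatenate([ub, -lb])
    keep = np.isfinite(b_ub)
    res = linprog(
        c,
        A_ub=a_ub[keep],
        b_ub=b_ub[keep],
        bounds=list(zip(_arr(prob["bounds_lb"]), _arr(prob["bounds_ub"]))),
        method="highs",
    )
    out = {"status": int(res.status), "message": str(res.message)}
    if res.x is not None:
        out["x"] = [float(v) for v in res.x]
        out["fun"] = float(res.fun)
    return out


def main():
    with open(sys.argv[1]) as fh:
        prob = json.load(fh)
    if prob["kind"] == "milp":
        out = solve_milp(prob)
    elif prob["kind"] == "lp_batch":
        out = {"results": [solve_lp(p) for p in prob["problems"]]}
    else:
        raise ValueError("unknown problem kind: %r" % prob["kind"])
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
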