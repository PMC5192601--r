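#!/usr/bin/env python
"""Batched LP backend for the plantflux R package.

Reads a JSON problem file, solves each LP with scipy's HiGHS interface and
writes a JSON result file.  Protocol (all indices 1-based, as emitted by R):

input: {"problems": [
   {"ncol": n,
    "rows": {"i": [...], "j": [...], "x": [...]},   # sparse constraint matrix
    "sense": ["E"|"L"|"G", ...],                    # one per row
    "rhs": [...],
    "lb": [...], "ub": [...],                       # +/-1e30 = unbounded
    "objectives": [{"c": [...dense...], "maximize": bool}, ...]
   }, ...]}

output: [[{"status": str, "objective": float, "x": [...],
           "dual_objective": float}, ...one per objective...], ...]
"""
import json
import sys

import numpy as np
from scipy.optimize import linprog
from scipy.sparse import coo_matrix

INF = 1e30


def solve_problem(prob):
    n = prob["ncol"]
    rows = prob.get("rows") or {"i": [], "j": [], "x": []}
    i = np.asarray(rows["i"], dtype=int) - 1
    j = np.asarray(rows["j"], dtype=int) - 1
    x = np.asarray(rows["x"], dtype=float)
    m = len(prob.get("sense", []))
    sense = np.asarray(prob.get("sense", []), dtype=object)
    rhs = np.asarray(prob.get("rhs", []), dtype=float)
    A = coo_matrix((x, (i, j)), shape=(m, n)).tocsr() if m else None
    lb = np.asarray(prob["lb"], dtype=float)
    ub = np.asarray(prob["ub"], dtype=float)
    lb = np.where(lb <= -INF, -np.inf, lb)
    ub = np.where(ub >= INF, np.inf, ub)
    bounds = np.column_stack([lb, ub])

    if m:
        eq = sense == "E"
        le = sense == "L"
        ge = sense == "G"
        A_eq = A[eq] if eq.any() else None
        b_eq = rhs[eq] if eq.any() else None
        A_ub_parts = []
        b_ub_parts = []
        if le.any():
            A_ub_parts.append(A[le])
            b_ub_parts.append(rhs[le])
        if ge.any():
            A_ub_parts.append(-A[ge])
            b_ub_parts.append(-rhs[ge])
        if A_ub_parts:
            from scipy.sparse import vstack
            A_ub = vstack(A_ub_parts)
            b_ub = np.concatenate(b_ub_parts)
        else:
            A_ub = None
            b_ub = None
    else:
        A_eq = b_eq = A_ub = b_ub = None

    results = []
    for obj in prob["objectives"]:
        c = np.asarray(obj["c"], dtype=float)
        mx = bool(obj.get("maximize", False))
        res = linprog(-c if mx else c, A_ub=A_ub, b_ub=b_ub, A_eq=A_eq,
                      b_eq=b_eq, bounds=bounds, method="highs")
        status = {0: "optimal", 1: "iteration_limit", 2: "infeasible",
                  3: "unbounded", 4: "numerical"}.get(res.status, "error")
        out = {"status": status}
        if res.status == 0:
            zval = float(res.fun)
            out["objective"] = -zval if mx else zval
            out["x"] = [float(v) for v in res.x]
            # dual objective for the certificate check
            try:
                dual = 0.0
                if b_eq is not None:
                    dual += float(np.dot(b_eq, res.eqlin.marginals))
                if b_ub is not None:
                    dual += float(np.dot(b_ub, res.ineqlin.marginals))
                lm = np.asarray(res.lower.marginals)
                um = np.asarray(res.upper.marginals)
                fin_l = np.isfinite(lb) & (lm != 0)
                fin_u = np.isfinite(ub) & (um != 0)
                dual += float(np.dot(lb[fin_l], lm[fin_l]))
                dual += float(np.dot(ub[fin_u], um[fin_u]))
                out["dual_objective"] = -dual if mx else dual
            except Exception:
                out["dual_objective"] = None
        results.append(out)
    return results


def main():
    infile, outfile = sys.argv[1], sys.argv[2]
    with open(infile) as fh:
        payload = json.load(fh)
    out = [solve_problem(p) for p in payload["problems"]]
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
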