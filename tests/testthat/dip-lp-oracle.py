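"""Independent dip oracle: direct LP minimization over unimodal CDFs.

For each mode position k (1..K over distinct values), solve
  min d  s.t. convex chain L_1..L_{k-1}, a within bands; concave chain
              b, R_{k+1}..R_K within bands; a <= b; values in [0,1].
dip = max(1/(2n), min_k LP_k).  Reads JSON list of samples on stdin
writes JSON list of dips on stdout.
"""
import sys, json
import numpy as np
from scipy.optimize import linprog


def dip_lp(sample):
    x = np.sort(np.asarray(sample, float))
    n = len(x)
    v, counts = np.unique(x, return_counts=True)
    K = len(v)
    p = np.concatenate([[0.0], np.cumsum(counts) / n])  # p[0..K]
    floor_d = 0.5 / n
    if K == 1:
        return floor_d
    best = np.inf
    for k in range(1, K + 1):
        # variables: d, L_1..L_{k-1}, a, b, R_{k+1}..R_K
        nL = k - 1
        nR = K - k
        nv = 1 + nL + 1 + 1 + nR
        iD = 0
        iL = lambda t: 1 + (t - 1)              # t = 1..k-1
        iA = 1 + nL
        iB = iA + 1
        iR = lambda t: iB + (t - k)             # t = k+1..K
        A, b_ub = [], []

        def add(row, rhs):
            A.append(row), b_ub.append(rhs)

        def band(idx, lo_p, hi_p):
            r = [0.0] * nv; r[idx] = -1.0; r[iD] = -1.0
            add(r, -lo_p)                       # val >= lo_p - d
            r = [0.0] * nv; r[idx] = 1.0; r[iD] = -1.0
            add(r, hi_p)                        # val <= hi_p + d

        # left chain: positions v[0..k-1], values L_1..L_{k-1}, a
        Lidx = [iL(t) for t in range(1, k)] + [iA]
        Lpos = [v[t] for t in range(k)]
        for t in range(1, k):
            band(iL(t), p[t], p[t - 1])
        band(iA, p[k - 1], p[k - 1])
        # monotone + convex
        for j in range(1, len(Lidx)):
            r = [0.0] * nv; r[Lidx[j]] = -1.0; r[Lidx[j - 1]] = 1.0
            add(r, 0.0)                         # nondecreasing
        for j in range(1, len(Lidx) - 1):
            d1 = Lpos[j] - Lpos[j - 1]
            d2 = Lpos[j + 1] - Lpos[j]
            # (y2-y1)/d2 >= (y1-y0)/d1
            r = [0.0] * nv
            r[Lidx[j + 1]] = -1.0 / d2
            r[Lidx[j]] = 1.0 / d2 + 1.0 / d1
            r[Lidx[j - 1]] = -1.0 / d1
            add(r, 0.0)
        # right chain: positions v[k-1..K-1], values b, R_{k+1}..R_K
        Ridx = [iB] + [iR(t) for t in range(k + 1, K + 1)]
        Rpos = [v[t] for t in range(k - 1, K)]
        band(iB, p[k], p[k])
        for t in range(k + 1, K + 1):
            band(iR(t), p[t], p[t - 1])
        for j in range(1, len(Ridx)):
            r = [0.0] * nv; r[Ridx[j]] = -1.0; r[Ridx[j - 1]] = 1.0
            add(r, 0.0)
        for j in range(1, len(Ridx) - 1):
            d1 = Rpos[j] - Rpos[j - 1]
            d2 = Rpos[j + 1] - Rpos[j]
            # concave: (y2-y1)/d2 <= (y1-y0)/d1
            r = [0.0] * nv
            r[Ridx[j + 1]] = 1.0 / d2
            r[Ridx[j]] = -1.0 / d2 - 1.0 / d1
            r[Ridx[j - 1]] = 1.0 / d1
            add(r, 0.0)
        # join a <= b
        r = [0.0] * nv; r[iA] = 1.0; r[iB] = -1.0
        add(r, 0.0)
        c = np.zeros(nv); c[iD] = 1.0
        bounds = [(0, None)] + [(0.0, 1.0)] * (nv - 1)
        res = linprog(c, A_ub=np.array(A), b_ub=np.array(b_ub), bounds=bounds,
                      method="highs",
                      options={"primal_feasibility_tolerance": 1e-10,
                               "dual_feasibility_tolerance": 1e-10})
        if res.status == 0:
            best = min(best, res.fun)
    return max(floor_d, best)


if __name__ == "__main__":
    samples = json.load(sys.stdin)
    print(json.dumps([dip_lp(s) for s in samples]))
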