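#!/usr/bin/env python
"""Independent reference implementation of IIT 3.0 big/small phi.

Purpose: an oracle, deliberately written in a different language and style
from the package's C++ engine, used to compute frozen reference values for
the test suite (see tools/make_phi_reference.R). Every earth-mover distance
is solved as an explicit transportation linear program with scipy's HiGHS
backend, including the effect side (the engine uses the product-form
shortcut there; the two must agree).

Conventions (must match src/phi_engine.cpp):
  * little-endian state bitmasks, bit i = node i, 1 = up;
  * repertoires indexed over purview nodes in ascending order;
  * mechanism partitions: unordered mechanism splits x ordered purview
    splits, a part may have an empty side but not both;
  * purview selection: maximal phi with tolerance 1e-6, ties to the larger
    purview, then to the smaller bitmask;
  * concepts kept when min(phi_cause, phi_effect) > 1e-6;
  * system cuts: all 2^n - 2 unidirectional severings, severed inputs
    replaced by maximum-entropy noise;
  * CES distance: transportation problem between concepts weighted by phi,
    ground metric = cause EMD + effect EMD of repertoires expanded over the
    full system, surplus mass exchanged with the null concept.

Usage:
  python iit3_reference.py phi CASES_CSV OUT_CSV
      CASES_CSV columns: case_id, tpm_path, state_code
      OUT_CSV   columns: case_id, phi
  python iit3_reference.py repertoire CASES_CSV OUT_CSV
      CASES_CSV columns: case_id, tpm_path, state_code, direction,
                         mechanism (";"-joined 1-based), purview (likewise)
      OUT_CSV   columns: case_id, index, value
"""

import csv
import sys

import numpy as np
from scipy.optimize import linprog

TIE = 1e-6
EPS = 1e-6


def popcount(x):
    return bin(x).count("1")


_cost_cache = {}


def hamming_cost(k):
    if k not in _cost_cache:
        m = 1 << k
        _cost_cache[k] = np.array(
            [[popcount(i ^ j) for j in range(m)] for i in range(m)], float
        )
    return _cost_cache[k]


def emd_lp(p, q, C):
    """Exact EMD between nonnegative vectors p, q under cost matrix C."""
    p = np.asarray(p, float)
    q = np.asarray(q, float)
    sa, sb = p.sum(), q.sum()
    if sa <= 1e-15 or sb <= 1e-15:
        return 0.0
    q = q * (sa / sb)
    m, n = C.shape
    # the last demand constraint is linearly dependent on the others; drop it
    # so floating-point total mismatches cannot render the system infeasible
    A_eq = np.zeros((m + n - 1, m * n))
    for i in range(m):
        A_eq[i, i * n:(i + 1) * n] = 1.0
    for j in range(n - 1):
        A_eq[m + j, j::n] = 1.0
    b_eq = np.concatenate([p, q[:-1]])
    res = linprog(C.ravel(), A_eq=A_eq, b_eq=b_eq, method="highs")
    if res.status != 0:
        raise RuntimeError("transportation LP failed: " + res.message)
    return float(res.fun)


def emd_hamming(p, q):
    k = int(round(np.log2(len(p))))
    return emd_lp(p, q, hamming_cost(k))


def bits_of(mask, n):
    return [b for b in range(n) if (mask >> b) & 1]


def compress(v, positions):
    out = 0
    for k, b in enumerate(positions):
        if (v >> b) & 1:
            out |= 1 << k
    return out


class Engine:
    def __init__(self, tpm, state):
        self.tpm = np.asarray(tpm, float)  # 2^n x n, P(node on | state)
        self.ns, self.n = self.tpm.shape
        assert self.ns == 1 << self.n
        self.state = state
        # likelihood of node i matching its current value given past v
        self.lk = np.empty((self.n, self.ns))
        for i in range(self.n):
            col = self.tpm[:, i]
            self.lk[i] = col if (state >> i) & 1 else 1.0 - col
        self.uncon = self.tpm.mean(axis=0)
        self._cause = {}
        self._effm = {}

    def cause_rep(self, mech, pv):
        key = (mech, pv)
        if key in self._cause:
            return self._cause[key]
        if pv == 0:
            out = np.ones(1)
        else:
            positions = bits_of(pv, self.n)
            np_ = 1 << len(positions)
            out = np.ones(np_) / np_
            if mech != 0:
                idx = np.array([compress(v, positions) for v in range(self.ns)])
                for i in bits_of(mech, self.n):
                    rho = np.zeros(np_)
                    np.add.at(rho, idx, self.lk[i])
                    s = rho.sum()
                    if s <= 0:
                        out = np.zeros(np_)
                        break
                    out = out * (rho / s)
                s = out.sum()
                out = out / s if s > 0 else out
        self._cause[key] = out
        return out

    def eff_marg(self, mech, j):
        key = (mech, j)
        if key in self._effm:
            return self._effm[key]
        fixed = self.state & mech
        sel = [v for v in range(self.ns) if (v & mech) == fixed]
        val = float(self.tpm[sel, j].mean())
        self._effm[key] = val
        return val

    def effect_rep(self, mech, pv):
        positions = bits_of(pv, self.n)
        np_ = 1 << len(positions)
        out = np.ones(np_)
        for k, b in enumerate(positions):
            pj = self.eff_marg(mech, b)
            bit = (np.arange(np_) >> k) & 1
            out = out * np.where(bit == 1, pj, 1.0 - pj)
        return out

    def partitions(self, mech, pv):
        """IIT 3.0 bipartitions of (mechanism, purview)."""
        low = mech & (-mech)
        rest = mech & ~low
        m1s = []
        m1 = rest
        while True:
            m1s.append(m1)
            if m1 == 0:
                break
            m1 = (m1 - 1) & rest
        p1s = []
        p1 = pv
        while True:
            p1s.append(p1)
            if p1 == 0:
                break
            p1 = (p1 - 1) & pv
        for m1 in m1s:
            m2 = mech & ~m1
            for p1 in p1s:
                p2 = pv & ~p1
                if (m1 | p1) != 0 and (m2 | p2) != 0:
                    yield m1, p1, m2, p2

    def partitioned_cause(self, m1, p1, m2, p2, pv):
        positions = bits_of(pv, self.n)
        np_ = 1 << len(positions)
        c1 = self.cause_rep(m1, p1)
        c2 = self.cause_rep(m2, p2)
        pos1 = [k for k, b in enumerate(positions) if (p1 >> b) & 1]
        pos2 = [k for k, b in enumerate(positions) if (p2 >> b) & 1]
        out = np.empty(np_)
        for u in range(np_):
            v1 = c1[compress(u, pos1)] if p1 else 1.0
            v2 = c2[compress(u, pos2)] if p2 else 1.0
            out[u] = v1 * v2
        return out

    def phi_purview(self, mech, pv, direction):
        if direction == "cause":
            whole = self.cause_rep(mech, pv)
            if whole.sum() <= 0:
                return 0.0
        else:
            whole = self.effect_rep(mech, pv)
        best = None
        for m1, p1, m2, p2 in self.partitions(mech, pv):
            if direction == "cause":
                part = self.partitioned_cause(m1, p1, m2, p2, pv)
                if part.sum() <= 0:
                    continue
                d = emd_hamming(whole, part)
            else:
                e1 = self.effect_rep(m1, p1) if p1 else None
                e2 = self.effect_rep(m2, p2) if p2 else None
                # joint product over the purview in ascending-node order
                positions = bits_of(pv, self.n)
                np_ = 1 << len(positions)
                pos1 = [k for k, b in enumerate(positions) if (p1 >> b) & 1]
                pos2 = [k for k, b in enumerate(positions) if (p2 >> b) & 1]
                part = np.empty(np_)
                for u in range(np_):
                    v1 = e1[compress(u, pos1)] if p1 else 1.0
                    v2 = e2[compress(u, pos2)] if p2 else 1.0
                    part[u] = v1 * v2
                d = emd_hamming(whole, part)
            if best is None or d < best:
                best = d
        return 0.0 if best is None else best

    def small_phi(self, mech, direction):
        evaluated = []
        for pv in range(1, self.ns):
            evaluated.append((pv, self.phi_purview(mech, pv, direction)))
        max_phi = max(phi for _, phi in evaluated)
        best_pv, best_phi = 0, 0.0
        for pv, phi in evaluated:
            if phi < max_phi - TIE:
                continue
            if (
                best_pv == 0
                or popcount(pv) > popcount(best_pv)
                or (popcount(pv) == popcount(best_pv) and pv < best_pv)
            ):
                best_pv, best_phi = pv, phi
        if max_phi <= 0:
            best_phi = 0.0
        return best_phi, best_pv

    def ces(self):
        concepts = []
        for mech in range(1, self.ns):
            phie, pve = self.small_phi(mech, "effect")
            if phie <= EPS:
                continue
            phic, pvc = self.small_phi(mech, "cause")
            if phic <= EPS:
                continue
            cause = self.cause_rep(mech, pvc)
            # expand over the full state space
            positions = bits_of(pvc, self.n)
            fill = (1 << len(positions)) / self.ns
            cause_full = np.array(
                [cause[compress(v, positions)] * fill for v in range(self.ns)]
            )
            effm = np.array(
                [
                    self.eff_marg(mech, j) if (pve >> j) & 1 else self.uncon[j]
                    for j in range(self.n)
                ]
            )
            concepts.append(
                dict(
                    mech=mech,
                    phi=min(phic, phie),
                    cause_full=cause_full,
                    effm=effm,
                )
            )
        return concepts


def expand_effect(effm):
    n = len(effm)
    ns = 1 << n
    out = np.ones(ns)
    for j in range(n):
        bit = (np.arange(ns) >> j) & 1
        out = out * np.where(bit == 1, effm[j], 1.0 - effm[j])
    return out


def concept_distance(c1, c2, n):
    dc = emd_hamming(c1["cause_full"], c2["cause_full"])
    de = emd_hamming(expand_effect(c1["effm"]), expand_effect(c2["effm"]))
    return dc + de


def ces_distance(C1, C2, null_concept, n):
    n1, n2 = len(C1), len(C2)
    if n1 == 0 and n2 == 0:
        return 0.0
    t1 = sum(c["phi"] for c in C1)
    t2 = sum(c["phi"] for c in C2)
    a = np.array([c["phi"] for c in C1] + [max(0.0, t2 - t1)])
    b = np.array([c["phi"] for c in C2] + [max(0.0, t1 - t2)])
    C = np.zeros((n1 + 1, n2 + 1))
    for i in range(n1):
        for j in range(n2):
            C[i, j] = concept_distance(C1[i], C2[j], n)
    for i in range(n1):
        C[i, n2] = concept_distance(C1[i], null_concept, n)
    for j in range(n2):
        C[n1, j] = concept_distance(C2[j], null_concept, n)
    return emd_lp(a, b, C)


def cut_tpm(tpm, from_mask, to_mask):
    ns, n = tpm.shape
    out = tpm.copy()
    subs = []
    sub = from_mask
    while True:
        subs.append(sub)
        if sub == 0:
            break
        sub = (sub - 1) & from_mask
    for j in range(n):
        if not (to_mask >> j) & 1:
            continue
        for v in range(ns):
            base = v & ~from_mask
            out[v, j] = np.mean([tpm[base | s, j] for s in subs])
    return out


def big_phi(tpm, state):
    tpm = np.asarray(tpm, float)
    ns, n = tpm.shape
    if n == 1:
        return 0.0
    eng = Engine(tpm, state)
    C1 = eng.ces()
    if not C1:
        return 0.0
    null_concept = dict(
        phi=0.0, cause_full=np.ones(ns) / ns, effm=eng.uncon.copy()
    )
    best = None
    for frm in range(1, ns - 1):
        to = (ns - 1) & ~frm
        t2 = cut_tpm(tpm, frm, to)
        if np.max(np.abs(t2 - tpm)) < 1e-15:
            d = 0.0
        else:
            C2 = Engine(t2, state).ces()
            d = ces_distance(C1, C2, null_concept, n)
        if best is None or d < best:
            best = d
        if best <= 1e-12:
            break
    return float(best)


def read_tpm_csv(path):
    with open(path) as fh:
        rows = [r for r in csv.reader(fh) if r]
    # optional header of non-numeric labels
    try:
        float(rows[0][0])
        data = rows
    except ValueError:
        data = rows[1:]
    return np.array([[float(x) for x in r] for r in data])


def main(argv):
    mode, cases_path, out_path = argv[1], argv[2], argv[3]
    with open(cases_path) as fh:
        cases = list(csv.DictReader(fh))
    out = []
    for case in cases:
        tpm = read_tpm_csv(case["tpm_path"])
        state = int(case["state_code"])
        if mode == "phi":
            phi = big_phi(tpm, state)
            out.append((case["case_id"], "%.12f" % phi))
            print(case["case_id"], phi, flush=True)
        elif mode == "repertoire":
            eng = Engine(tpm, state)
            mech = sum(1 << (int(i) - 1) for i in case["mechanism"].split(";"))
            pv = sum(1 << (int(i) - 1) for i in case["purview"].split(";"))
            rep = (
                eng.cause_rep(mech, pv)
                if case["direction"] == "cause"
                else eng.effect_rep(mech, pv)
            )
            for idx, val in enumerate(rep):
                out.append((case["case_id"], idx, "%.15e" % val))
        else:
            raise SystemExit("unknown mode: " + mode)
    with open(out_path, "w", newline="") as fh:
        w = csv.writer(fh)
        if mode == "phi":
            w.writerow(["case_id", "phi"])
        else:
            w.writerow(["case_id", "index", "value"])
        w.writerows(out)


if __name__ == "__main__":
    main(sys.argv)
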