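#!/usr/bin/env python
"""Independent reference implementation of the empirical wavelet transform.

Written from the published algorithm description (midpoint boundaries
between the N largest spectral maxima; Meyer-type filters with
transition half-width lambda_n = gamma * omega_n; modes as the per-band
tight-frame reconstruction components) using NumPy only, sharing no code
with the R package.  Used once to freeze cross-check fixtures:

    python tools/ewt_oracle.py two_tone   > tests/testthat/fixtures/ewt_oracle_two_tone.csv
    python tools/ewt_oracle.py three_tone > tests/testthat/fixtures/ewt_oracle_three_tone.csv

Each CSV has one column per mode, header mode_1..mode_N.
"""
import sys
import numpy as np


def beta(x):
    x = np.clip(x, 0.0, 1.0)
    return x ** 4 * (35 - 84 * x + 70 * x ** 2 - 20 * x ** 3)


def segment(x, n_seg):
    n = len(x)
    mag = np.abs(np.fft.fft(x))[: n // 2 + 1]
    # local maxima, DC/Nyquist excluded
    cand = [i for i in range(1, len(mag) - 1) if mag[i] > mag[i - 1] and mag[i] >= mag[i + 1]]
    cand.sort(key=lambda i: (-mag[i], i))
    sel = sorted(cand[:n_seg])
    w = 2 * np.pi * np.array(sel) / n
    return (w[1:] + w[:-1]) / 2


def filter_bank(bounds, n, gamma):
    j = np.arange(n)
    w = np.minimum(2 * np.pi * j / n, 2 * np.pi - 2 * np.pi * j / n)
    edges = list(bounds) + [np.pi]
    N = len(edges)
    resp = np.zeros((n, N))
    for k in range(N):
        lo = None if k == 0 else edges[k - 1]
        hi = None if k == N - 1 else edges[k]
        r = np.ones(n)
        if lo is not None:
            lam = gamma * lo
            r = np.where(w < lo - lam, 0.0,
                         np.where(w <= lo + lam,
                                  np.sin(np.pi / 2 * beta((w - (lo - lam)) / (2 * lam))), r))
        if hi is not None:
            lam = gamma * hi
            r = np.where(w > hi + lam, 0.0,
                         np.where(w >= hi - lam,
                                  np.minimum(r, np.cos(np.pi / 2 * beta((w - (hi - lam)) / (2 * lam)))), r))
        resp[:, k] = r
    return resp


def ewt(x, n_seg, gamma=None):
    bounds = segment(x, n_seg)
    edges = np.concatenate([bounds, [np.pi]])
    gaps = np.diff(edges) / (edges[1:] + edges[:-1])
    gmax = min(1.0, gaps.min()) if len(gaps) else 1.0
    if gamma is None:
        gamma = 0.9 * gmax
    resp = filter_bank(bounds, len(x), gamma)
    X = np.fft.fft(x)
    return np.real(np.fft.ifft(X[:, None] * resp ** 2, axis=0)), bounds


def main(which):
    if which == "two_tone":
        k = np.arange(640)
        x = np.cos(0.2 * np.pi * k) + np.cos(0.6 * np.pi * k)
        modes, bounds = ewt(x, 2)
    elif which == "three_tone":
        k = np.arange(640)
        x = (np.cos(0.2 * np.pi * k) + np.cos(0.5 * np.pi * k)
             + np.cos(0.8 * np.pi * k))
        modes, bounds = ewt(x, 3)
    else:
        raise SystemExit("unknown fixture: " + which)
    sys.stderr.write("boundaries/pi: %s\n" % (bounds / np.pi))
    print(",".join("mode_%d" % (i + 1) for i in range(modes.shape[1])))
    for row in modes:
        print(",".join("%.10g" % v for v in row))


if __name__ == "__main__":
    main(sys.argv[1])
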