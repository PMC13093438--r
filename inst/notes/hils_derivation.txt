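Derivation note: the outgroup-anchored invariants test and gamma estimator
==========================================================================

Setup
-----
A quartet (O, P1, H, P2) with O an outgroup to the three ingroup taxa, and H
a putative hybrid whose genome traces P1's history with probability gamma and
P2's with probability 1 - gamma (hybrid-speciation model on top of the
multispecies coalescent).

Each alignment site with unambiguous bases in all four positions is assigned
to one of the 15 set-partition classes of the four bases, written with the
outgroup labelled A:

  AAAA AAAB AABA AABB AABC ABAA ABAB ABAC ABBA ABBB ABBC ABCA ABCB ABCC ABCD

Only three classes enter the test:

  ABBA : P1 = H  share a state different from O = P2   ("H sticks to P1")
  AABB : H = P2  share a state different from O = P1   ("H sticks to P2")
  ABAB : P1 = P2 share a state different from O = H    (double-discordant)

Invariants
----------
Under a purely treelike history ((P1,H),P2) with an internal branch of
length t (coalescent units), ILS produces the two minor arrangements with
equal probability, and homoplasy on terminal branches of equal depth is
symmetric, so

  E[p_AABB] = E[p_ABAB]            =>  E[X2] = 0,  X2 = n_AABB - n_ABAB,

while the concordant excess makes E[X1] > 0, X1 = n_ABBA - n_ABAB.
Mirror statements hold under (P1,(H,P2)): E[X1] = 0, E[X2] > 0.
Under hybridization with 0 < gamma < 1, the site-pattern distribution is the
gamma-mixture of the two parental histories, hence BOTH linear invariants
have positive expectation:

  E[X1] ~ gamma * c,    E[X2] ~ (1 - gamma) * c,

where c collects the (equal, by the symmetric attachment assumption)
concordant excess of the two parental quartet geometries.

gamma estimator
---------------
  gamma_hat = X1 / (X1 + X2)

tends to 1 when H is sister to P1 (X2 -> 0) and to 0 when H is sister to P2;
swapping P1 and P2 swaps X1 and X2 and maps gamma_hat to 1 - gamma_hat
exactly. Values outside [0,1] can occur under model violation (negative
invariants); they are clamped for reporting and flagged, with the raw value
retained.

Test statistic
--------------
Treat the three class counts as multinomial with N = sites used. Then

  Var(X1) = N [ p9(1-p9) + p7(1-p7) + 2 p9 p7 ]
  Var(X2) = N [ p4(1-p4) + p7(1-p7) + 2 p4 p7 ]
  Cov(X1,X2) = N [ -p9 p4 + p9 p7 + p4 p7 + p7(1-p7) ]

with p9 = p_ABBA, p7 = p_ABAB, p4 = p_AABB (indices are the positions of the
classes in the list above). With the plug-in ratio r = X2 / X1,

  z = X2 / sqrt( r^2 Var(X1) - 2 r Cov(X1,X2) + Var(X2) )

i.e. the numerator r*X1 = X2 studentized by the variance of r*X1 - X2 at
fixed r. Behaviour at the tree-like boundaries:

  r -> 0   (H sister to P1):  z -> X2 / sd(X2),   E = 0
  r -> inf (H sister to P2):  z -> X1 / sd(X1),   E = 0

so z is asymptotically (sub-)standard normal under either no-hybridization
arrangement and grows like sqrt(N) when both invariants are positive. The
p-value is one-sided, P = 1 - Phi(z). When X1 = 0 exactly, 1 is added to
both counts (the reference implementation's guard); a non-positive variance
combination yields an "undefined" flagged result rather than a zero.

Caveats
-------
Unequal terminal rates (e.g., one fast lineage) inflate ABBA and AABB
convergences jointly and can produce z > 0 without hybridization with
gamma_hat near 0.5; this is exactly the false-positive mode the
null-simulation filter addresses by re-simulating on the empirical
substitution-unit tree. The implementation is validated by type-I
calibration, gamma recovery, the P1/P2 swap identity, and power
monotonicity in the test suite, so a coefficient transcription error would
be detectable there rather than hidden.
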