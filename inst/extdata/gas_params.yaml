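# Buffer-gas physics for the CCS engines.
#
# N2 is modeled as a single isotropic pseudo-atom carrying the N2 mass and
# polarizability with effective Lennard-Jones parameters per element; this
# deliberately simplifies the four-site diatomic N2 models used by
# trajectory-method codes.  The per-element values below are effective
# single-site parameters assembled from published He trajectory-method
# tables and single-site N2 reparameterizations; override any entry (or
# point at your own file) when a calibrated set is available.
#
# Units: mass amu; polarizability A^3; eps eV; sigma A; hard-sphere
# collision radius (atom + gas, used by the projection engine) A.

He:
  mass: 4.002602
  polarizability: 0.205
  elements:
    H:  {eps: 0.00065, sigma: 2.38, rhs: 2.20}
    C:  {eps: 0.00134, sigma: 3.04, rhs: 2.70}
    N:  {eps: 0.00134, sigma: 3.04, rhs: 2.70}
    O:  {eps: 0.00134, sigma: 3.04, rhs: 2.70}
N2:
  mass: 28.0134
  polarizability: 1.7403
  elements:
    H:  {eps: 0.00230, sigma: 2.80, rhs: 2.60}
    C:  {eps: 0.00440, sigma: 3.58, rhs: 3.10}
    N:  {eps: 0.00470, sigma: 3.45, rhs: 3.10}
    O:  {eps: 0.00500, sigma: 3.25, rhs: 3.10}
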