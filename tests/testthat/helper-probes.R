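# Expected pepsin (pH > 2) cleavage sites for a panel of probe sequences,
# derived by hand from the packaged rule table: cut when P1 is F/L/W/Y with
# P1' not P and P2 not H/K/R, or when P1' is F/L/W/Y with P1 not P, P2 not
# H/K/R and P2' not P; out-of-window positions pass forbidden-set and fail
# allowed-set constraints. Site i is the bond after residue i. Frozen before
# the engine ran on them.
probe_panel <- list(
  GGGGG = integer(),            # no bulky hydrophobic residue
  AAFAA = c(2L, 3L),            # both sides of the F
  AYPA = integer(),             # P in P1' blocks the P1-side rule
  AAFPA = integer(),            # P blocks both rules around the F
  AHFAA = 2L,                   # P2 = H blocks the C-side cut only
  AKLAA = 2L,                   # P2 = K likewise
  WAAAW = c(1L, 4L),            # terminal windows pass forbidden sets
  TSKYR = 3L,                   # P2 = K blocks the cut after the Y
  LVVYPW = 1L,
  LVVYPWTQ = c(1L, 6L),
  VVYPWTQ = 5L,
  FLSFPTTKTYFPH = c(1L, 2L, 10L)
)
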