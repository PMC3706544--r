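# Fixture finite-state melody grammar (documented substitute, not a
# reconstruction of any published grammar). Two tagged pathways leave the
# shared start state S0 and rejoin at the shared accept state F. Loops are
# bounded so enumeration to 15 terminal pairs is finite (276 sequences of
# 8-30 tones; 252 upper-pathway, 24 lower-pathway).
#
# Terminals are tone pairs over eight pitches spanning one octave (60-72).
states: [S0, U1, U2, U3, L1, L2, L3, F]
start: S0
accepts: [F]
pathways:
  upper: [U1, U2, U3]
  lower: [L1, L2, L3]
transitions:
  - [S0, a, U1]
  - [U1, b, U2]
  - [U1, c, U2]
  - [U2, d, U1]
  - [U2, e, U3]
  - [U3, f, F]
  - [U3, g, F]
  - [S0, h, L1]
  - [L1, g, L2]
  - [L2, f, L2]
  - [L2, e, L3]
  - [L3, d, F]
  - [L3, c, F]
terminals:
  a: [60, 62]
  b: [62, 64]
  c: [64, 65]
  d: [65, 67]
  e: [67, 69]
  f: [69, 71]
  g: [71, 72]
  h: [72, 67]
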