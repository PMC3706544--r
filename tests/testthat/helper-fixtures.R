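# Small grammars and datasets built in code for the test suite.

minimal_grammar <- function() {
  load_grammar(list(states = c("S0", "S1"), start = "S0", accepts = "S1",
                    transitions = list(c("S0", "a", "S1")),
                    terminals = list(a = c(60, 64))))
}

loop_grammar <- function() {
  load_grammar(list(states = "S0", start = "S0", accepts = "S0",
                    transitions = list(c("S0", "a", "S0")),
                    terminals = list(a = c(60, 62))))
}

# four-pitch alphabet for cheap exhaustive mapping tests
mini_alphabet <- function() {
  agl_alphabet(list(a = c(60, 62), b = c(62, 64), c = c(64, 65)))
}

# a tiny response/manifest pair with known structure: 2 grammatical and
# 2 ungrammatical stimuli
toy_manifest <- function() {
  data.frame(id = c("g1", "g2", "u1", "u2"),
             category = c("old_gram", "new_gram", "ungram", "ungram"),
             error_type = c(NA, NA, 1L, 5L),
             label_sequence = c("a-b", "b-a", "a-a", "b-b"),
             pitch_csv = c("60,62,62,64", "62,64,60,62",
                           "60,62,60,62", "62,64,62,64"),
             n_tones = 4L, stringsAsFactors = FALSE)
}

toy_responses <- function(familiar) {
  man <- toy_manifest()
  data.frame(participant = "p1", stimulus = man$id,
             familiar = familiar, stringsAsFactors = FALSE)
}
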