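# Shorthand constructors used across the test files.

profile <- function(p53 = 0, p16 = 0, p27 = 0, cerbB2 = 0, id = "P01",
                    role = "primary") {
  SpecimenProfile(id, role, c(p53 = p53, p16 = p16, p27 = p27,
                              cerbB2 = cerbB2))
}

pairFromD <- function(p53 = 0, p16 = 0, p27 = 0, cerbB2 = 0, id = "pair") {
  PairDValue(id, c(p53 = p53, p16 = p16, p27 = p27, cerbB2 = cerbB2))
}

randomDeciles <- function(n) sample(seq(0L, 100L, by = 10L), n, replace = TRUE)
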