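# In-code fixtures shared across the test files.

make_spectra <- function(wl = 300:700, ...) {
  as_spectra(data.frame(wl = wl, ...))
}

# ramp rising 0 -> 100 across 300-700 nm
ramp_spectrum <- function(wl = 300:700) (wl - 300) / 4

# logistic cut-on centred at `centre`
sigmoid_spectrum <- function(centre, wl = 300:700, scale = 15,
                             base = 5, amp = 80) {
  base + amp / (1 + exp(-(wl - centre) / scale))
}

flat_illuminant <- function(wl = 300:700, value = 1) {
  illuminant(wl, rep(value, length(wl)), name = "flat")
}

toy_tetra_vs <- function(weber = 0.05, eta = c(1, 1, 1, 4)) {
  visual_system("toy", c(uv = 367, sw = 456, mw = 497, lw = 562),
                eta = eta, weber_ref = weber)
}

# minimal hand-built catch table (bypasses spectra) for distance tests
make_catch_table <- function(f, achro_f, e, weber_achro = 0.05,
                             ids = paste0("id", seq_len(nrow(f)))) {
  Q <- exp(f)
  structure(list(ids = ids, Q = Q, f = f, qrel = Q / rowSums(Q),
                 achro_Q = exp(achro_f), achro_f = achro_f,
                 e = e, weber_achro = weber_achro,
                 vs = "toy", ill = "flat"),
            class = "catch_table")
}

tiny_meta <- function(ids, morphs, sexes = rep("M", length(ids))) {
  as_metadata(data.frame(individual_id = ids, morph = morphs, sex = sexes))
}
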