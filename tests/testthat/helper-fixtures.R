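# Small shared fixtures, built in code at test time.

# a fast, low-budget GA configuration for unit tests
quick_ga <- function(seed = 1, ...) {
  args <- utils::modifyList(list(population_size = 60, max_generations = 120,
                                 stall_generations = 40, seed = seed),
                            list(...))
  do.call(ga_config, args)
}

# a short synthetic subject for structural tests (not recovery experiments)
quick_subject <- function(seed = 101, duration = 6, ...) {
  make_subject(synth_config(seed = seed, duration = duration, ...))
}

# analytic Ishigami function and its variance decomposition (a = 7, b = 0.1)
ishigami <- function(X) {
  sin(X[, 1]) + 7 * sin(X[, 2])^2 + 0.1 * X[, 3]^4 * sin(X[, 1])
}

ishigami_analytic <- function(a = 7, b = 0.1) {
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  V <- V1 + V2 + V13
  list(S1 = c(V1 / V, V2 / V, 0),
       ST = c((V1 + V13) / V, V2 / V, V13 / V))
}

unit_box <- function(d) list(lower = rep(0, d), upper = rep(1, d))
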