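# Desk-scale version of the single-cell study design: mature size reduced
# to 1000 cells, all other rates as in the full design (maturity at 5 y,
# total homeostatic division rate 5 /y with 40% asymmetric, 1.2 mutations
# per daughter per division).
desk_params <- function(NM = 1000, NH = min(50, floor(NM / 4))) {
  model_params(NM = NM, tM = 5, NH = NH, lam = 5, p = 0.4, mu = 1.2)
}

# Build a genealogy object by hand from parent links and per-branch
# mutation counts (for small enumerable cases).
manual_genealogy <- function(parent, nmut, alive, t = 1) {
  structure(list(parent = as.integer(parent), nmut = as.integer(nmut),
                 alive = as.integer(alive), t = t, N = length(alive),
                 n_events = NA_real_,
                 params = model_params(NM = max(2, length(alive)), tM = 1),
                 seed = NULL),
            class = "genealogy")
}

# Exact expected sampled spectrum of a single variant at population
# abundance j, by enumeration of all C(N, S) subsets.
enumerate_sampled <- function(N, j, S) {
  subsets <- utils::combn(N, S)
  carriers <- seq_len(j)
  counts <- numeric(S + 1)
  for (c in seq_len(ncol(subsets))) {
    i <- sum(subsets[, c] %in% carriers)
    counts[i + 1] <- counts[i + 1] + 1
  }
  counts / ncol(subsets)   # index i+1 holds expected V~(i)
}
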