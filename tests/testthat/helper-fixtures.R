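# In-code fixtures shared across test files.

# Two-site toy community: consumers A@{s1,s2}, B@{s2}; resources x@{s1},
# y@{s2}; one recorded interaction (s1, A, x).
toy_csv_files <- function(dir = tempfile("toy")) {
  dir.create(dir)
  occ <- data.frame(
    site = c("s1", "s2", "s2", "s1", "s2"),
    guild = c("consumer", "consumer", "consumer", "resource", "resource"),
    species = c("A", "A", "B", "x", "y"))
  inter <- data.frame(site = "s1", consumer = "A", resource = "x")
  occ_path <- file.path(dir, "occurrences.csv")
  int_path <- file.path(dir, "interactions.csv")
  write.csv(occ, occ_path, row.names = FALSE)
  write.csv(inter, int_path, row.names = FALSE)
  list(occ = occ_path, inter = int_path, dir = dir)
}

toy_dataset <- function() {
  paths <- toy_csv_files()
  load_dataset(paths$occ, paths$inter, name = "toy", interaction_type = "PP")
}

# random frequency matrix with every consumer co-occurring somewhere
random_freq_matrix <- function(n_cons, n_res, max_count = 3, seed = 1) {
  set.seed(seed)
  repeat {
    N <- matrix(sample(0:max_count, n_cons * n_res, replace = TRUE),
                nrow = n_cons,
                dimnames = list(paste0("c", seq_len(n_cons)),
                                paste0("r", seq_len(n_res))))
    if (all(rowSums(N) >= 1)) return(N)
  }
}

# Independent oracle for the conditional expected link count: enumerate all
# link configurations of each consumer's row (rows are independent), weight
# each by its Bernoulli probability with per-pair probability 1-(1-p)^N_ai,
# discard the all-empty configuration, renormalize, and accumulate the
# expected number of links.
enumerate_expected_links <- function(N, p) {
  total <- 0
  for (a in seq_len(nrow(N))) {
    probs <- 1 - (1 - p)^N[a, ]
    k <- length(probs)
    exp_links <- 0
    norm <- 0
    for (code in seq_len(2^k) - 1L) {
      config <- as.integer(intToBits(code))[seq_len(k)]
      if (sum(config) == 0L) next
      w <- prod(ifelse(config == 1L, probs, 1 - probs))
      exp_links <- exp_links + w * sum(config)
      norm <- norm + w
    }
    total <- total + exp_links / norm
  }
  total
}

# small fast metacommunity for pipeline tests
small_metacommunity <- function(seed = 1, true_p = 0.1) {
  simulate_metacommunity(n_sites = 15, n_consumers = 25, n_resources = 35,
                         true_p = true_p, seed = seed)
}
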