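# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- force(expr)
  }
  .fixture_cache[[name]]
}

tiny_study <- function() {
  cached("tiny", suppressMessages(make_fixture("tiny", seed = 101)))
}

# mid-size study: big enough for variance-component work, small enough for
# repeated animal-model fits
small_study <- function() {
  cached("small", suppressMessages(generate_breeding_data(sim_config(
    n_seasons = 10, n_founder_females = 22, n_founder_males = 22,
    second_release_females = 0, second_release_males = 0,
    carrying_cap = 35, seed = 202
  ))))
}

default_study <- function() {
  cached("default", suppressMessages(
    generate_breeding_data(sim_config(seed = 303))))
}

# simple random pedigree for property tests: founders plus random matings
random_pedigree <- function(n_founders, n_offspring, seed) {
  set.seed(seed)
  ids <- paste0("I", seq_len(n_founders + n_offspring))
  dam <- sire <- rep(NA_character_, n_founders + n_offspring)
  for (k in seq_len(n_offspring)) {
    i <- n_founders + k
    pool <- seq_len(i - 1)
    dam[i] <- ids[sample(pool, 1)]
    sire[i] <- ids[sample(pool, 1)]
  }
  tibble::tibble(id = ids, dam = dam, sire = sire)
}

# gene-dropping oracle: expected allele-sharing between individuals equals
# the additive relationship; estimated by dropping biallelic founder genomes
gene_drop_relationship <- function(pedigree, n_rep = 20000, seed = 1) {
  set.seed(seed)
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- match(as.character(ped$dam), id)
  sire <- match(as.character(ped$sire), id)
  n <- length(id)
  # each individual = 2 gametes; founder gametes globally unique labels
  acc <- matrix(0, n, n)
  for (r in seq_len(n_rep)) {
    g1 <- integer(n); g2 <- integer(n)
    lab <- 0L
    for (i in seq_len(n)) {
      if (is.na(dam[i])) { lab <- lab + 1L; g1[i] <- lab }
      else g1[i] <- if (runif(1) < 0.5) g1[dam[i]] else g2[dam[i]]
      if (is.na(sire[i])) { lab <- lab + 1L; g2[i] <- lab }
      else g2[i] <- if (runif(1) < 0.5) g1[sire[i]] else g2[sire[i]]
    }
    for (i in seq_len(n)) {
      share <- (outer(g1, g1[i], "==") + outer(g1, g2[i], "==") +
                  outer(g2, g1[i], "==") + outer(g2, g2[i], "==")) / 2
      acc[, i] <- acc[, i] + share
    }
  }
  A <- acc / n_rep
  dimnames(A) <- list(id, id)
  A
}
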