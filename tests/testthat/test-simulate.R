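test_that("pure-birth trees have the requested shape and are deterministic", {
  cfg <- simulation_config(n_genomes = 4, seed = 1)
  tr <- simulate_tree(cfg)
  expect_equal(length(tr$tip.label), 4)
  expect_equal(tr$Nnode, 3)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(simulate_tree(cfg)), ape::write.tree(tr))
})

test_that("mean tree height matches a direct Monte-Carlo pure-birth oracle", {
  n <- 10; lambda <- 1
  heights <- vapply(1:500, function(s) {
    tr <- simulate_tree(simulation_config(n_genomes = n, birth_rate = lambda,
                                          seed = s))
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  # oracle: independent simulation of the waiting-time sums
  set.seed(99)
  orc <- vapply(1:20000, function(i)
    sum(rexp(n - 1, rate = (2:n) * lambda)), numeric(1))
  se <- sqrt(var(heights) / length(heights) + var(orc) / length(orc))
  expect_lt(abs(mean(heights) - mean(orc)), 3 * se)
})

test_that("trait evolution respects absorbing states and symmetry", {
  cfg0 <- simulation_config(n_genomes = 8, q01 = 0, q10 = 0.5, seed = 3)
  tr <- simulate_tree(cfg0)
  tra <- simulate_trait(tr, cfg0, root_state = "negative")
  expect_true(all(tra == "negative"))  # gains impossible
  # symmetric rates on long branches: leaf states fair coin
  star <- ape::stree(2000, type = "star")
  star$edge.length <- rep(50, nrow(star$edge))
  cfg1 <- simulation_config(n_genomes = 2000, q01 = 1, q10 = 1, seed = 4)
  tra1 <- simulate_trait(star, cfg1)
  frac <- mean(tra1[star$tip.label] == "positive")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("branch transition frequencies match the matrix exponential", {
  # one fixed branch, compared against a brute-force small-step simulation
  q01 <- 0.3; q10 <- 0.7; t <- 1.5
  star <- ape::stree(4000, type = "star")
  star$edge.length <- rep(t, nrow(star$edge))
  cfg <- simulation_config(n_genomes = 4000, q01 = q01, q10 = q10, seed = 8)
  tra <- simulate_trait(star, cfg, root_state = "negative")
  p_hat <- mean(tra[star$tip.label] == "positive")
  # analytic CTMC probability
  pi1 <- q01 / (q01 + q10)
  p_exact <- pi1 * (1 - exp(-(q01 + q10) * t))
  # small-step simulation oracle
  set.seed(123)
  nstep <- 3000; dt <- t / nstep
  sim_once <- function() {
    s <- 0
    for (k in seq_len(nstep))
      s <- if (s == 0) rbinom(1, 1, q01 * dt) else 1 - rbinom(1, 1, q10 * dt)
    s
  }
  p_oracle <- mean(vapply(1:2000, function(i) sim_once(), numeric(1)))
  expect_lt(abs(p_hat - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 4000))
  expect_lt(abs(p_oracle - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2000))
})

test_that("degenerate Brownian counts are Poisson around the base mean", {
  cfg <- simulation_config(n_genomes = 200, n_features = 50, bm_sigma2 = 0,
                           effect_beta = 0, frac_linked = 0,
                           base_log_mean = log(2), seed = 5)
  tr <- simulate_tree(cfg)
  tra <- simulate_trait(tr, cfg)
  cnt <- simulate_counts(tr, tra, cfg)
  mu <- mean(cnt$matrix)
  n <- length(cnt$matrix)
  expect_lt(abs(mu - 2), 3 * sqrt(2 / n))
  expect_identical(cnt$linked, character(0))
})

test_that("linked features show the multiplicative trait effect", {
  cfg <- simulation_config(n_genomes = 400, n_features = 40, bm_sigma2 = 0.001,
                           effect_beta = 2, frac_linked = 0.5,
                           base_log_mean = 0, q01 = 1, q10 = 1, seed = 6)
  tr <- simulate_tree(cfg)
  tra <- simulate_trait(tr, cfg)
  cnt <- simulate_counts(tr, tra, cfg)
  pos <- names(tra[tr$tip.label])[tra[tr$tip.label] == "positive"]
  neg <- setdiff(tr$tip.label, pos)
  ratio <- mean(cnt$matrix[pos, cnt$linked]) / mean(cnt$matrix[neg, cnt$linked])
  expect_gt(ratio, exp(2) * 0.7)
  expect_lt(ratio, exp(2) * 1.4)
})

test_that("ORF layouts conserve the copy-number matrix", {
  cfg <- simulation_config(n_genomes = 10, n_features = 12, seed = 7)
  d <- simulate_dataset(cfg)
  for (acc in d$genomes$accession) {
    o <- d$orfs[d$orfs$genome == acc, ]
    tab <- table(unlist(o$features))
    tab <- tab[!names(tab) %in% c("rubisco", "prk")]
    row <- d$matrix[acc, ]; row <- row[row > 0]
    expect_setequal(names(tab), names(row))
    expect_identical(as.integer(tab[names(row)]), unname(as.integer(row)))
  }
  # a zero matrix yields unannotated ORFs
  zero <- d$matrix; zero[] <- 0L
  orfs0 <- simulate_orfs(d$genomes, zero, cfg)
  expect_true(all(lengths(orfs0$features) == 0))
})

test_that("certain co-location places linked copies adjacent to markers", {
  cfg <- simulation_config(n_genomes = 12, n_features = 6, co_prob = 1,
                           frac_linked = 0.5, effect_beta = 1, seed = 9)
  d <- simulate_dataset(cfg)
  pos <- d$genomes$accession[d$genomes$trait_status == "positive"]
  tuples <- orf_distances(d$orfs, c("rubisco", "prk"), genomes = pos)
  linked_t <- tuples[tuples$Feature %in% d$linked, ]
  expect_gt(nrow(linked_t), 0)
  med <- tapply(linked_t$Distance, linked_t$Feature, median)
  expect_true(all(med <= 2))
})

test_that("identical config and seed give byte-identical written datasets", {
  cfg <- simulation_config(n_genomes = 12, n_features = 8, seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})
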