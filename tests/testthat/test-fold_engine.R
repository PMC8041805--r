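test_that("energy model validates its invariants", {
  m <- energy_model()
  expect_s3_class(m, "energy_model")
  expect_identical(m$kT, 0.6)
  expect_error(energy_model(pair_energies = c(GC = 1, AU = -2, GU = -1)),
               "negative")
  expect_error(energy_model(min_hairpin = 2), "min_hairpin")
  expect_error(energy_model(kT = 0), "kT")
  expect_error(energy_model(allow_lone_pairs = FALSE), "lone pairs")
})

test_that("fold_mfe handles trivial and constrained cases", {
  expect_equal(fold_mfe("AAAAAA"), list(structure = "......", energy = 0))
  expect_equal(fold_mfe("GGGAAAACCC", constraint = "xxxxxxxxxx"),
               list(structure = "..........", energy = 0))
  bf <- brute_force_fold("GGGAAAACCC")
  mfe <- fold_mfe("GGGAAAACCC")
  expect_equal(mfe$energy, min(bf$energy))
  expect_true(mfe$structure %in% bf$structure[bf$energy == min(bf$energy)])
  expect_error(fold_mfe("ACGX"), "invalid nucleotide")
  # '|' forces pairing where none is possible: must be reported, not relaxed
  expect_error(fold_mfe("AAAAAA", constraint = "|....."), "unsatisfiable")
})

test_that("partition function matches enumeration and includes open chain", {
  pf <- partition_function("AAAAAA", want_bpp = FALSE)
  expect_equal(pf$z, 1)
  expect_equal(pf$ensemble_energy, 0)
  m <- energy_model()
  bf <- brute_force_fold("GGGAAAACCC", m)
  pf2 <- partition_function("GGGAAAACCC", m, want_bpp = FALSE)
  expect_equal(pf2$z, sum(exp(-bf$energy / m$kT)), tolerance = 1e-9)
})

test_that("DP engine agrees with the brute-force oracle on random inputs", {
  set.seed(101)
  m <- energy_model()
  for (rep in 1:60) {
    s <- random_rna(sample(6:16, 1))
    bf <- brute_force_fold(s, m)
    w <- exp(-bf$energy / m$kT)
    z_oracle <- sum(w)
    mfe <- fold_mfe(s, m)
    pf <- partition_function(s, m, want_bpp = TRUE)
    expect_equal(mfe$energy, min(bf$energy), tolerance = 1e-9)
    expect_equal(pf$z, z_oracle, tolerance = 1e-9)
    n <- nchar(s)
    pb <- matrix(0, n, n)
    for (q in seq_len(nrow(bf))) {
      pt <- parse_dotbracket(bf$structure[q])
      op <- which(pt$partner > seq_len(n))
      pb[cbind(op, pt$partner[op])] <- pb[cbind(op, pt$partner[op])] + w[q]
    }
    expect_lt(max(abs(pb / z_oracle - pf$bp_prob)), 1e-8)
    # row sums of pair probabilities never exceed 1
    expect_true(all(pf$bp_prob + t(pf$bp_prob) >= -1e-12))
    expect_true(all(rowSums(pf$bp_prob + t(pf$bp_prob)) <= 1 + 1e-9))
  }
})

test_that("constraints never increase the partition function", {
  set.seed(202)
  m <- energy_model()
  for (rep in 1:30) {
    s <- random_rna(sample(8:16, 1))
    n <- nchar(s)
    cons <- rep(".", n)
    cons[sample(n, sample(1:3, 1))] <- "x"
    cons <- paste(cons, collapse = "")
    z0 <- partition_function(s, m, want_bpp = FALSE)$z
    z1 <- partition_function(s, m, constraint = cons, want_bpp = FALSE)$z
    expect_lte(z1, z0 + 1e-12)
  }
})

test_that("ensemble metrics satisfy their identities", {
  m <- energy_model()
  # single-state ensemble
  em0 <- ensemble_metrics(0, 0, m$kT, matrix(0, 6, 6))
  expect_equal(em0$mfe_frequency, 1)
  expect_equal(em0$ensemble_diversity, 0)
  s <- "GGGAAAACCC"
  mfe <- fold_mfe(s, m)
  pf <- partition_function(s, m)
  em <- ensemble_metrics(mfe$energy, pf$log_z, m$kT, pf$bp_prob)
  expect_gt(em$mfe_frequency, 0)
  expect_lte(em$mfe_frequency, 1)
  # log-space identity: freq * Z = exp(-E/kT)
  expect_equal(log(em$mfe_frequency) + pf$log_z, -mfe$energy / m$kT,
               tolerance = 1e-9)
  # diversity against the enumeration oracle (expected symmetric difference)
  bf <- brute_force_fold(s, m)
  w <- exp(-bf$energy / m$kT); w <- w / sum(w)
  pts <- lapply(bf$structure, function(db) {
    pt <- parse_dotbracket(db)$partner
    which(pt > seq_along(pt)) * 1000L + pt[pt > seq_along(pt)]
  })
  k <- length(pts)
  d_oracle <- 0
  for (a in 1:k) for (b in 1:k)
    d_oracle <- d_oracle + w[a] * w[b] *
      length(c(setdiff(pts[[a]], pts[[b]]), setdiff(pts[[b]], pts[[a]])))
  expect_equal(em$ensemble_diversity, d_oracle, tolerance = 1e-8)
})

test_that("brute_force_fold enumerates exactly the valid structures", {
  bf <- brute_force_fold("ACGU")
  expect_equal(nrow(bf), 1L)
  expect_equal(bf$structure, "....")
  expect_equal(bf$energy, 0)
  s <- "GGGAAAACCC"
  expect_equal(nrow(brute_force_fold(s)), count_structures_oracle(s))
  bfx <- brute_force_fold(s, constraint = "xxxxxxxxxx")
  expect_equal(nrow(bfx), 1L)
  expect_error(brute_force_fold(strrep("A", 30)), "max_len")
})

test_that("active conformation probability respects its bounds", {
  m <- energy_model()
  # no pairs possible, no constraint: E_wt = 0, Z = 1, divisor 1
  r <- active_conformation_probability("AAAAAA", m, "......", "......")
  expect_equal(r$probability, 1)
  expect_equal(r$noncanonical_core_count, 0L)

  # 30-nt synthetic hairpin with a 2-bp core
  seqn <- "GGCGAAGGGCAAAAGCCCAAAAAACGCCAA"
  wt <- fold_mfe(seqn, m)$structure
  pt <- parse_dotbracket(wt)$partner
  core_i <- head(which(pt > seq_along(pt)), 2)
  ref <- rep(".", 30); cons <- rep(".", 30)
  ref[core_i] <- "("; ref[pt[core_i]] <- ")"
  cons[pt[core_i]] <- ">"
  ref <- paste(ref, collapse = ""); cons <- paste(cons, collapse = "")
  p_wt <- active_conformation_probability(seqn, m, cons, ref)
  expect_true(p_wt$satisfiable)
  expect_gt(p_wt$probability, 0)
  # make both core pairs noncanonical (G -> A against C partners)
  v <- strsplit(seqn, "")[[1]]
  v[core_i] <- "A"
  # only mutate where the partner cannot pair A (partner C)
  stopifnot(all(v[pt[core_i]] == "C"))
  var <- paste(v, collapse = "")
  p_var <- active_conformation_probability(var, m, cons, ref)
  expect_equal(p_var$noncanonical_core_count, 2L)
  if (p_var$satisfiable) expect_gt(p_wt$probability, p_var$probability)

  # unsatisfiable constraint is a flagged missing value, not an error
  p_un <- active_conformation_probability("AAAAAAAAAA", m,
                                          paste(rep(c(".", ">"), 5),
                                                collapse = ""),
                                          strrep(".", 10))
  expect_false(p_un$satisfiable)
  expect_true(is.na(p_un$probability))
})

test_that("folding is deterministic", {
  set.seed(303)
  for (rep in 1:20) {
    s <- random_rna(sample(10:20, 1))
    expect_identical(fold_mfe(s), fold_mfe(s))
  }
})

test_that("the external adapter is backend-agnostic", {
  s <- "GGGAAAACCCAAGGGCAAAGCCC"
  a <- external_fold_adapter(s, backend = "builtin")
  b <- fold_sequence(s)
  expect_identical(a$mfe_structure, b$mfe_structure)
  expect_identical(a$mfe_energy, b$mfe_energy)
  expect_identical(nchar(a$mfe_structure), nchar(s))
  # round-trip: adapter output parses
  expect_s3_class(parse_dotbracket(a$mfe_structure), "pair_table")
  if (nzchar(Sys.which("RNAfold"))) {
    v <- external_fold_adapter(s, backend = "vienna")
    expect_identical(nchar(v$mfe_structure), nchar(s))
  } else {
    expect_error(external_fold_adapter(s, backend = "vienna"), "RNAfold")
  }
})
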