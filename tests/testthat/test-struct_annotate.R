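test_that("parse_dotbracket round-trips pairs and rejects bad input", {
  pt <- parse_dotbracket("((...))")
  expect_equal(pt$partner, c(7L, 6L, 0L, 0L, 0L, 2L, 1L))
  expect_equal(parse_dotbracket(".......")$partner, rep(0L, 7))
  expect_error(parse_dotbracket("(()"), "unbalanced")
  expect_error(parse_dotbracket("(.]"), "illegal")
})

test_that("annotate_elements segments canonical cases correctly", {
  kinds <- function(db, seqn = NULL)
    vapply(annotate_elements(parse_dotbracket(db), seqn), `[[`, character(1),
           "kind")
  e1 <- annotate_elements(parse_dotbracket("(((...)))"))
  expect_equal(kinds("(((...)))"), c("stem", "hairpin"))
  expect_equal(e1[[1]]$dims, 3L)
  expect_equal(e1[[2]]$dims, 3L)

  e2 <- annotate_elements(parse_dotbracket("((.((...)).))"))
  expect_equal(kinds("((.((...)).))"),
               c("stem", "internal", "stem", "hairpin"))
  expect_equal(e2[[2]]$dims, c(1L, 1L))

  e3 <- annotate_elements(parse_dotbracket("((.((...))))"))
  expect_equal(kinds("((.((...))))"), c("stem", "bulge", "stem", "hairpin"))
  expect_equal(e3[[2]]$dims, c(1L, 0L))

  # multiloop with two branches plus exterior
  db4 <- ".((..((...))..((...))..))."
  k4 <- kinds(db4)
  expect_true("multiloop" %in% k4)
  expect_true("exterior" %in% k4)
})

test_that("segmentation is a partition and round-trips, on folded structures", {
  set.seed(404)
  for (rep in 1:100) {
    s <- random_rna(sample(15:40, 1))
    db <- fold_mfe(s)$structure
    els <- annotate_elements(parse_dotbracket(db), s)
    pos <- unlist(lapply(els, `[[`, "positions"))
    expect_equal(sort(pos), seq_len(nchar(s)))
    expect_false(anyDuplicated(pos) > 0)
    expect_identical(elements_to_dotbracket(els, nchar(s)), db)
  }
})

test_that("site context identifies the A:C mismatch configuration", {
  sub <- fixture_substrate()
  els <- annotate_elements(parse_dotbracket(sub$wt_structure),
                           sub$wt_sequence)
  ctx <- locate_site_context(els, sub$editing_site, sub$wt_sequence)
  expect_equal(ctx$site$kind, "internal")
  expect_equal(ctx$site$dims, c(1L, 1L))
  expect_identical(ctx$opposing_nt, "C")
  expect_false(is.null(ctx$u1)); expect_false(is.null(ctx$d1))

  # editing site in a terminal hairpin loop: no downstream elements
  seqn3 <- "GGGGAAAAACCCC"
  db3 <- "((((.....))))"
  els3 <- annotate_elements(parse_dotbracket(db3), seqn3)
  ctx3 <- locate_site_context(els3, 6L, seqn3)
  expect_equal(ctx3$site$kind, "hairpin")
  expect_null(ctx3$d1); expect_null(ctx3$d2); expect_null(ctx3$d3)

  # editing site paired in a stem: opposing is the Watson-Crick partner
  seqn4 <- "GGGAAAAACCCU"
  db4 <- "(((.....)))."
  ctx4 <- locate_site_context(annotate_elements(parse_dotbracket(db4),
                                                seqn4), 2L, seqn4)
  expect_equal(ctx4$site$kind, "stem")
  expect_identical(ctx4$opposing_nt, "C")
  expect_error(locate_site_context(els3, 99L, seqn3), "out of range")
})

test_that("to_tree preserves element counts and ordering", {
  for (db in c("(((...)))", "((.((...)).))",
               ".((..((...))..((...))..)).")) {
    els <- annotate_elements(parse_dotbracket(db))
    tr <- to_tree(els)
    expect_equal(length(tr$labels), length(els))
  }
})

test_that("similarity score: identity, symmetry, oracle agreement", {
  sub <- fixture_substrate()
  tr <- to_tree(annotate_elements(parse_dotbracket(sub$wt_structure),
                                  sub$wt_sequence))
  expect_identical(similarity_score(tr, tr), 1)

  a <- nested_as_tree(list(label = "hairpin[3]", children = list()))
  b <- nested_as_tree(list(label = "stem[4]", children = list()))
  expect_gte(similarity_score(a, b), 0)
  expect_lt(similarity_score(a, b), 1)
  expect_equal(similarity_score(a, b), similarity_score(b, a))

  # random small trees against the independent forest-edit oracle
  set.seed(505)
  rand_nested <- function(depth) {
    lab <- sample(c("stem[2]", "stem[3]", "hairpin[4]", "internal[1:1]",
                    "bulge[1:0]"), 1)
    nk <- if (depth <= 0) 0 else sample(0:2, 1)
    list(label = lab,
         children = lapply(seq_len(nk), function(i) rand_nested(depth - 1)))
  }
  for (rep in 1:25) {
    t1 <- rand_nested(2); t2 <- rand_nested(2)
    d_pkg <- tree_edit_distance(nested_as_tree(t1), nested_as_tree(t2))
    d_orc <- forest_edit_oracle(list(t1), list(t2))
    expect_equal(d_pkg, d_orc)
  }
})

test_that("inserting elements strictly decreases similarity", {
  base <- list(label = "stem[4]", children = list(
    list(label = "hairpin[4]", children = list())))
  grow <- function(t, k) {
    # nest k extra bulge elements above the hairpin
    if (k == 0) return(t)
    grow(list(label = "stem[4]", children = list(
      list(label = "bulge[1:0]", children = t$children))), k - 1)
  }
  t0 <- nested_as_tree(base)
  sims <- vapply(1:3, function(k)
    similarity_score(t0, nested_as_tree(grow(base, k))), numeric(1))
  expect_true(all(diff(sims) < 0))
  expect_true(all(sims < 1))
})

test_that("stem_length_summary totals stems", {
  sl <- function(db) stem_length_summary(annotate_elements(
    parse_dotbracket(db)))
  expect_equal(sl("(((...)))"), 3)
  expect_equal(sl("......"), 0)
  expect_equal(sl("((.((...)).))"), 4)
})
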