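test_that("expert aggregation is the entry-wise arithmetic mean", {
  m <- pcm_rows(list(c("E", "HI"), c("1/HI", "E")), c("a", "b"))
  # idempotence on identical matrices
  agg <- aggregate_experts(list(m, m, m))
  expect_equal(agg$entries, m$entries, ignore_attr = TRUE)
  expect_equal(agg$source, "aggregate")

  m2 <- pcm_rows(list(c("E", "VI"), c("1/VI", "E")), c("a", "b"))
  agg2 <- aggregate_experts(list(m, m2))
  expect_equal(as.numeric(agg2$entries["a", "b", ]), c(4, 6, 8))
  expect_equal(as.numeric(agg2$entries["a", "a", ]), c(1, 1, 1))

  # mean of HI, HI, EI judgments
  m3 <- pcm_rows(list(c("E", "EI"), c("1/EI", "E")), c("a", "b"))
  agg3 <- aggregate_experts(list(m, m, m3))
  expect_equal(as.numeric(agg3$entries["a", "b", ]),
               c(13 / 3, 19 / 3, 23 / 3))

  expect_error(aggregate_experts(list(m, pcm_rows(list(c("E", "VI"),
                                                       c("1/VI", "E")),
                                                  c("x", "y")))),
               "share the same labels")
})

test_that("Buckley weights reproduce the study's worked duration example", {
  m <- pcm_rows(list(c("E", "VI"), c("1/VI", "E")), c("C31", "C32"))
  fw <- buckley_weights(m)
  expect_equal(unname(fw$geometric_means["C31", ]),
               c(sqrt(5), sqrt(7), sqrt(9)), tolerance = 1e-12)
  expect_equal(unname(fw$geometric_means["C32", ]),
               c(1 / 3, 1 / sqrt(7), 1 / sqrt(5)), tolerance = 1e-12)
  # printed as (0.64, 0.87, 1.17) after truncation
  expect_near(unname(fw$fuzzy_weights["C31", ]), c(0.64, 0.87, 1.17))
  w <- crisp_weights(fw)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_near(unname(w), c(0.88, 0.12))

  # symmetric judgment gives equal degenerate weights
  sym <- pcm_rows(list(c("E", "E"), c("E", "E")), c("a", "b"))
  fws <- buckley_weights(sym)
  expect_equal(unname(fws$fuzzy_weights), matrix(0.5, 2, 3),
               ignore_attr = TRUE)
})

test_that("Buckley path agrees with the symbol-by-symbol oracle to 1e-12", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(2:4, 1)
    m <- pairwise_matrix(random_term_matrix(n))
    got <- crisp_weights(buckley_weights(m))
    want <- oracle_buckley(pcm_as_lists(m))$crisp
    expect_equal(unname(got), want, tolerance = 1e-12)
    fw <- buckley_weights(m)
    for (i in seq_len(n)) {
      expect_equal(unname(fw$fuzzy_weights[i, ]),
                   oracle_buckley(pcm_as_lists(m))$w[[i]], tolerance = 1e-12)
    }
    expect_equal(sum(got), 1, tolerance = 1e-9)
  }
})

test_that("consistent crisp matrices are recovered exactly with CR zero", {
  w <- c(a = 0.6, b = 0.3, c = 0.1)
  m <- generate_consistent_matrix(w)
  expect_equal(crisp_weights(buckley_weights(m)), w, tolerance = 1e-9)
  cr <- consistency_ratio(m)
  expect_equal(cr$consistency_ratio, 0, tolerance = 1e-9)
  expect_equal(cr$lambda_max, 3, tolerance = 1e-9)
  expect_true(cr$acceptable)
})

test_that("consistency ratio follows Saaty's eigenvalue method", {
  # any 2x2 reciprocal matrix is perfectly consistent
  m2 <- pcm_rows(list(c("E", "EI"), c("1/EI", "E")), c("a", "b"))
  expect_equal(consistency_ratio(m2)$consistency_ratio, 0)
  expect_equal(consistency_ratio(m2)$random_index, 0)

  # a defuzzified matrix with known eigenstructure: the report's lambda_max
  # must match a direct eigen computation on the centroid matrix
  m <- pairwise_matrix(random_term_matrix(4, paste0("k", 1:4)))
  crisp <- apply(m$entries, c(1, 2), mean)
  lam <- max(Re(eigen(crisp)$values))
  rep4 <- consistency_ratio(m, defuzz = "centroid")
  expect_equal(rep4$lambda_max, lam, tolerance = 1e-12)
  expect_equal(rep4$consistency_ratio, (lam - 4) / 3 / 0.9, tolerance = 1e-12)
  expect_equal(rep4$random_index, 0.9)

  # alternative defuzzification rules are exposed
  expect_false(identical(consistency_ratio(m, "modal")$lambda_max,
                         rep4$lambda_max))
  expect_error(consistency_ratio(pairwise_matrix(matrix("E", 1, 1,
                                                        dimnames = list("a", "a")))),
               "n >= 2")
})

test_that("local alternative weights mirror the published per-column values", {
  fx <- load_study_fixture()
  cons <- fx$panel$experts$consensus$pairwise
  alt_ms <- cons[paste0("alts:", study_subs)]
  names(alt_ms) <- study_subs
  locals <- local_alternative_weights(alt_ms)  # centroid rule
  expect_equal(dim(locals), c(3, 8))
  # the duration-of-operation column as published
  expect_near(unname(locals[, "C31"]), c(0.08, 0.57, 0.45), tol = 0.02)

  # all-equal judgments give equal normalized weights
  eq <- pcm_rows(list(c("E", "E", "E"), c("E", "E", "E"), c("E", "E", "E")),
                 c("A1", "A2", "A3"))
  leq <- local_alternative_weights(list(s = eq), defuzz = "sum_normalized")
  expect_equal(unname(leq[, "s"]), rep(1 / 3, 3), tolerance = 1e-12)

  # consistent matrix recovers its generating weights under normalization
  m <- generate_consistent_matrix(c(A1 = 0.6, A2 = 0.3, A3 = 0.1))
  lrec <- local_alternative_weights(list(s = m), defuzz = "sum_normalized")
  expect_equal(unname(lrec[, "s"]), c(0.6, 0.3, 0.1), tolerance = 1e-6)
})

test_that("hierarchical synthesis reproduces the published global scores", {
  fx <- load_study_fixture()
  pub <- fx$published
  main <- pub$main_weights
  subs <- split(pub$sub_weights, parent_criteria(fx$hierarchy)[study_subs])
  locals <- pub$local_weights  # alternatives x sub-criteria
  scores <- synthesize_global_scores(main, subs, locals)
  expect_near(unname(scores["A3"]), 0.29)
  expect_near(unname(scores["A2"]), 0.69)
  expect_near(unname(scores["A1"]), 0.36)

  # telescoping: locals all 1/m give every alternative 1/m
  flat <- matrix(1 / 3, 3, 8, dimnames = list(c("A1", "A2", "A3"), study_subs))
  s2 <- synthesize_global_scores(main / sum(main), lapply(subs, function(x) x),
                                 flat)
  expect_equal(unname(s2), rep(1 / 3, 3), tolerance = 1e-9)
})

test_that("weights are equivariant under relabeling of criteria", {
  m <- pairwise_matrix(random_term_matrix(4, c("p", "q", "r", "s")))
  w <- crisp_weights(buckley_weights(m))
  perm <- c(3, 1, 4, 2)
  arr <- m$entries[perm, perm, , drop = FALSE]
  mp <- pairwise_matrix(arr, labels = m$labels[perm])
  wp <- crisp_weights(buckley_weights(mp))
  expect_equal(wp, w[m$labels[perm]], tolerance = 1e-12)
})

test_that("ranking orders by score, breaks ties by input order and flags them", {
  r <- rank_alternatives(c(A1 = 0.36, A2 = 0.69, A3 = 0.29))
  expect_equal(r$alternative, c("A2", "A1", "A3"))
  expect_equal(r$rank, 1:3)
  expect_false(any(r$tied))

  r2 <- rank_alternatives(c(x = 1, y = 1, z = 0.5))
  expect_equal(r2$alternative[1:2], c("x", "y"))
  expect_true(all(r2$tied[1:2]))
  expect_equal(r2$rank[1:2], c(1, 1))

  r3 <- rank_alternatives(c(a = 1, b = 2, c = 3))
  expect_equal(r3$alternative, c("c", "b", "a"))
})
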