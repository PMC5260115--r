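make_ratings <- function(rows, alts = c("A1", "A2", "A3"), subs = study_subs) {
  m <- do.call(rbind, rows)
  rownames(m) <- alts[seq_len(nrow(m))]
  colnames(m) <- subs[seq_len(ncol(m))]
  m
}

expert3_ratings <- function() {
  load_study_fixture()$panel$experts$E3$ratings
}

test_that("linguistic ratings decode to the scale's fuzzy numbers", {
  r <- expert3_ratings()
  panel <- build_decision_matrix(r, expert = "E3")
  expect_equal(as.numeric(panel$values["A2", "C21", ]), c(7, 10, 10))  # VG
  expect_equal(as.numeric(panel$values["A1", "C41", ]), c(0, 2.5, 5))  # P

  allp <- make_ratings(list(rep("P", 8), rep("P", 8), rep("P", 8)))
  pp <- build_decision_matrix(allp)
  expect_true(all(apply(pp$values, c(1, 2), function(v)
    identical(as.numeric(v), c(0, 2.5, 5)))))

  bad <- r; bad["A1", "C11"] <- "XX"
  expect_error(build_decision_matrix(bad, expert = "E3"),
               "expert 'E3'.*'A1'.*'C11'")
})

test_that("scale-max normalization reproduces the published normalized matrix", {
  panel <- build_decision_matrix(expert3_ratings())
  norm <- normalize_ratings(panel)  # divide by 10
  expect_equal(as.numeric(norm$values["A1", "C11", ]), c(0.25, 0.5, 0.75))
  expect_equal(as.numeric(norm$values["A2", "C21", ]), c(0.7, 1, 1))
  expect_equal(as.numeric(norm$values["A3", "C12", ]), c(0.7, 1, 1))
  # an entry equal to the divisor in all components maps to (1,1,1)
  ten <- build_decision_matrix(make_ratings(list(rep("VG", 8))))
  ten$values["A1", "C11", ] <- c(10, 10, 10)
  expect_equal(as.numeric(normalize_ratings(ten)$values["A1", "C11", ]),
               c(1, 1, 1))
})

test_that("extremal normalization honours benefit and cost directions", {
  r <- make_ratings(list(c("G", "F"), c("VG", "P"), c("F", "G")),
                    subs = c("C11", "C12"))
  panel <- build_decision_matrix(r)
  dirs <- c(C11 = "benefit", C12 = "cost")
  expect_error(normalize_ratings(panel, divisor_rule = "extremal",
                                 directions = dirs),
               "non-positive")  # P has lower component 0 on a cost criterion
  dirs2 <- c(C11 = "benefit", C12 = "benefit")
  norm <- normalize_ratings(panel, divisor_rule = "extremal",
                            directions = dirs2)
  # benefit: (l/u*, m/m*, u/l*) with column maxima (7,10,10) under C11
  expect_equal(as.numeric(norm$values["A1", "C11", ]),
               c(5 / 10, 7.5 / 10, 10 / 7))
  # ordering preserved everywhere
  expect_true(all(apply(norm$values, c(1, 2), function(v)
    v[1] <= v[2] && v[2] <= v[3])))

  # genuine cost criterion with positive entries
  r2 <- make_ratings(list(c("G", "F"), c("VG", "G"), c("F", "G")),
                     subs = c("C11", "C12"))
  norm2 <- normalize_ratings(build_decision_matrix(r2),
                             divisor_rule = "extremal",
                             directions = c(C11 = "benefit", C12 = "cost"))
  # a_j- = 2.5 (the F rating's lower bound); F maps to (2.5/7.5, 2.5/5, 2.5/2.5)
  expect_equal(as.numeric(norm2$values["A1", "C12", ]),
               c(2.5 / 7.5, 0.5, 1))
})

test_that("hierarchical weighting reproduces the published weighted matrix", {
  fx <- load_study_fixture()
  w3 <- criterion_weights(fx$panel$experts$E3$pairwise, fx$hierarchy)
  panel <- build_decision_matrix(fx$panel$experts$E3$ratings)
  norm <- normalize_ratings(panel)
  wm <- apply_weights(norm, w3$main, w3$subs)

  # the worked A3/C31 value
  expect_near(as.numeric(wm$values["A3", "C31", ]), c(0.011, 0.022, 0.033),
              tol = 5e-4)
  # A1/C22 at full precision sits within print rounding of the table
  # (the table itself was computed from 2-dp weights, hence the 3e-3 slack)
  expect_near(as.numeric(wm$values["A1", "C22", ]), c(0.136, 0.273, 0.410),
              tol = 3e-3)

  # weight product of one is the identity on the grid
  unit <- apply_weights(norm, c(C = 1),
                        list(C = stats::setNames(rep(1, 8), study_subs)))
  # (parents of all criteria under the single main "C")
  expect_equal(unit$values, norm$values, ignore_attr = TRUE)
})

test_that("published weighted table is matched at the table's own precision", {
  # the published table was tabulated from the study's 2-dp weight prints;
  # feeding those published weights back in matches every component to 2e-3
  fx <- load_study_fixture()
  main2 <- fx$published$expert3_main_weights
  sub2 <- fx$published$expert3_sub_weights
  subs2 <- split(sub2, parent_criteria(fx$hierarchy)[study_subs])
  norm <- normalize_ratings(build_decision_matrix(fx$panel$experts$E3$ratings))
  wm <- apply_weights(norm, main2, subs2)
  tab8_A1 <- rbind(c(0.018, 0.036, 0.054), c(0.002, 0.004, 0.006),
                   c(0.056, 0.084, 0.112), c(0.136, 0.273, 0.410),
                   c(0.011, 0.022, 0.033), c(0.003, 0.004, 0.006),
                   c(0.000, 0.021, 0.042), c(0.031, 0.063, 0.094))
  tab8_A2 <- rbind(c(0.036, 0.054, 0.072), c(0.004, 0.006, 0.008),
                   c(0.078, 0.112, 0.112), c(0.273, 0.410, 0.547),
                   c(0.022, 0.033, 0.044), c(0.004, 0.006, 0.006),
                   c(0.021, 0.042, 0.063), c(0.063, 0.094, 0.126))
  expect_near(unname(wm$values["A1", , ]), unname(tab8_A1), tol = 2e-3)
  expect_near(unname(wm$values["A2", , ]), unname(tab8_A2), tol = 2e-3)
})

test_that("ideal solutions support fixed and extremal modes", {
  fx <- load_study_fixture()
  w3 <- criterion_weights(fx$panel$experts$E3$pairwise, fx$hierarchy)
  wm <- apply_weights(normalize_ratings(
    build_decision_matrix(fx$panel$experts$E3$ratings)), w3$main, w3$subs)

  fixed <- ideal_solutions(wm, mode = "fixed")
  expect_true(all(fixed$positive == 1))
  expect_true(all(fixed$negative == 0))

  ext <- ideal_solutions(wm, mode = "extremal")
  for (cc in wm$criteria) {
    expect_equal(ext$positive[cc, ], apply(wm$values[, cc, ], 2, max))
    expect_equal(ext$negative[cc, ], apply(wm$values[, cc, ], 2, min))
  }

  # single alternative: both ideals collapse onto its row
  one <- wm
  one$values <- wm$values["A1", , , drop = FALSE]
  one$alternatives <- "A1"
  exo <- ideal_solutions(one, mode = "extremal")
  expect_equal(exo$positive, exo$negative)
})

test_that("the two distance variants differ exactly by sqrt(3)", {
  expect_near(separation_distance(tfn(0.011, 0.022, 0.033), tfn(1, 1, 1)),
              0.565, tol = 5e-4)
  expect_near(separation_distance(tfn(0.011, 0.022, 0.033), tfn(0, 0, 0)),
              0.014, tol = 5e-4)
  expect_equal(separation_distance(tfn(0.2, 0.4, 0.6), tfn(0.2, 0.4, 0.6)), 0)

  set.seed(7)
  for (i in 1:25) {
    v <- sort(runif(3)); u <- sort(runif(3))
    p <- separation_distance(tfn(v[1], v[2], v[3]), tfn(u[1], u[2], u[3]),
                             variant = "study")
    x <- separation_distance(tfn(v[1], v[2], v[3]), tfn(u[1], u[2], u[3]),
                             variant = "vertex")
    expect_equal(p, x / sqrt(3), tolerance = 1e-15)
  }
})

test_that("separation measures sum per-criterion distances", {
  fx <- load_study_fixture()
  w3 <- criterion_weights(fx$panel$experts$E3$pairwise, fx$hierarchy)
  ts <- topsis_stage(fx$panel$experts$E3$ratings, w3, h = fx$hierarchy,
                     expert = "E3")
  meas <- ts$measures
  expect_equal(meas$S_positive, rowSums(meas$D_positive), tolerance = 1e-12)
  expect_equal(meas$S_negative, rowSums(meas$D_negative), tolerance = 1e-12)
  # worked values: A3's distances to the ideals under C31
  expect_near(unname(meas$D_positive["A3", "C31"]), 0.565, tol = 5e-4)
  expect_near(unname(meas$D_negative["A3", "C31"]), 0.014, tol = 5e-4)

  # all-zero entries against fixed ideals: S* = k/3 * sqrt(3) per criterion
  wm0 <- ts$weighted
  wm0$values[] <- 0
  m0 <- separation_measures(wm0, ideal_solutions(wm0, "fixed"), "study")
  expect_equal(unname(m0$S_positive), rep(8 * sqrt(3) / 3, 3),
               tolerance = 1e-12)
  expect_equal(unname(m0$S_negative), rep(0, 3))
})

test_that("closeness coefficients rank by relative separation", {
  cc <- closeness(list(S_positive = c(A1 = 4.268, A2 = 4.194, A3 = 4.331),
                       S_negative = c(A1 = 0.378, A2 = 0.446, A3 = 0.317)))
  expect_equal(cc$cc[cc$alternative == "A3"], 0.317 / (4.331 + 0.317))
  expect_equal(cc$alternative, c("A2", "A1", "A3"))
  expect_true(all(cc$cc >= 0 & cc$cc <= 1))

  edge <- closeness(list(S_positive = c(1, 0), S_negative = c(0, 1)))
  expect_equal(sort(edge$cc), c(0, 1))
  expect_error(closeness(list(S_positive = 0, S_negative = 0)), "degenerate")
})

test_that("closeness is monotone in benefit ratings under fixed ideals", {
  fx <- load_study_fixture()
  w3 <- criterion_weights(fx$panel$experts$E3$pairwise, fx$hierarchy)
  terms <- c("P", "F", "G", "VG")
  set.seed(99)
  for (i in 1:10) {
    r <- make_ratings(list(sample(terms, 8, TRUE), sample(terms, 8, TRUE),
                           sample(terms, 8, TRUE)))
    base_cc <- topsis_stage(r, w3, h = fx$hierarchy)$closeness
    a <- sample(rownames(r), 1)
    j <- sample(colnames(r), 1)
    pos <- match(r[a, j], terms)
    if (pos == length(terms)) next
    r2 <- r
    r2[a, j] <- terms[pos + 1]
    up_cc <- topsis_stage(r2, w3, h = fx$hierarchy)$closeness
    expect_gte(up_cc$cc[up_cc$alternative == a],
               base_cc$cc[base_cc$alternative == a])
  }
})

test_that("a uniformly best-rated alternative attains the highest closeness", {
  fx <- load_study_fixture()
  w3 <- criterion_weights(fx$panel$experts$E3$pairwise, fx$hierarchy)
  r <- make_ratings(list(rep("P", 8), rep("VG", 8), rep("P", 8)))
  cc <- topsis_stage(r, w3, h = fx$hierarchy)$closeness
  expect_equal(cc$alternative[1], "A2")
  expect_gt(cc$cc[1], max(cc$cc[-1]))
})
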