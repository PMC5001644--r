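# Loss/gain probability calculus and variant scoring.

test_that("loss given stable follows the product formula", {
  expect_equal(loss_given_stable(1, 0), 1)
  expect_equal(loss_given_stable(0, 0.7), 0)
  expect_equal(loss_given_stable(0.99, 3.3e-3), 0.99 * (1 - 3.3e-3))
  expect_equal(loss_given_stable(0.99, 3.3e-3), 0.986733)
  expect_error(loss_given_stable(1.2, 0.5), "\\[0, 1\\]")
})

test_that("gain given stable follows the mirrored product formula", {
  expect_equal(gain_given_stable(0, 1), 1)
  expect_equal(gain_given_stable(1, 0.4), 0)
  expect_equal(gain_given_stable(3.8e-4, 0.99), (1 - 3.8e-4) * 0.99)
  expect_equal(gain_given_stable(3.8e-4, 0.99), 0.9896238)
})

test_that("marginal loss interpolates the two stability strata", {
  expect_equal(loss_marginal(0.8, 0.5, 0), loss_given_stable(0.8, 0.5))
  expect_equal(loss_marginal(0.8, 0.5, 1), 0.8)
  expect_equal(loss_marginal(0.8, 0.5, 0.25), 0.8 * 0.25 + 0.8 * 0.5 * 0.75)
  expect_equal(loss_marginal(0.8, 0.5, 0.25), 0.5)
})

test_that("marginal gain vanishes under certain stability disruption", {
  expect_equal(gain_marginal(0.1, 0.9, 1), 0)
  expect_equal(gain_marginal(0.1, 0.9, 0), gain_given_stable(0.1, 0.9))
  expect_equal(gain_marginal(0.1, 0.9, 0.5), 0.405)
})

test_that("combination models behave on singletons, pairs and absorbing values", {
  expect_equal(combine_independence(0.4), 0.4)
  expect_equal(combine_independence(c(0.5, 0.5)), 0.75)
  expect_equal(combine_independence(c(0.2, 1, 0.3)), 1)
  expect_equal(combine_max(0.4), 0.4)
  expect_equal(combine_max(c(0.2, 0.7, 0.1)), 0.7)
  expect_error(combine_independence(numeric()), "empty")
  expect_error(combine_max(numeric()), "empty")
})

test_that("all outputs stay in [0,1] and the documented monotonicities hold", {
  set.seed(50)
  for (rep in 1:1000) {
    p_wt <- runif(1); p_mt <- runif(1); p_S <- runif(1)
    pr <- mechanism_probabilities(p_wt, p_mt, p_S)
    expect_true(all(pr >= 0 & pr <= 1))
    # identity: loss_joint = loss_stable * (1 - p_S)
    expect_equal(unname(pr["loss_joint"]),
                 unname(pr["loss_stable"]) * (1 - p_S), tolerance = 1e-12)
    # gain marginal equals gain joint (no gain under disruption)
    expect_equal(unname(pr["gain_marginal"]), unname(pr["gain_joint"]))
    # loss_marginal - loss_joint = p_wt * p_S >= 0
    expect_equal(unname(pr["loss_marginal"] - pr["loss_joint"]),
                 p_wt * p_S, tolerance = 1e-12)

    # monotonicity spot checks by small perturbation
    eps <- 0.01
    if (p_wt < 0.99) {
      expect_gte(loss_marginal(p_wt + eps, p_mt, p_S) -
                   loss_marginal(p_wt, p_mt, p_S), -1e-12)
      expect_lte(gain_marginal(p_wt + eps, p_mt, p_S) -
                   gain_marginal(p_wt, p_mt, p_S), 1e-12)
    }
    if (p_mt < 0.99) {
      expect_lte(loss_marginal(p_wt, p_mt + eps, p_S) -
                   loss_marginal(p_wt, p_mt, p_S), 1e-12)
      expect_gte(gain_marginal(p_wt, p_mt + eps, p_S) -
                   gain_marginal(p_wt, p_mt, p_S), -1e-12)
    }
  }
})

test_that("the max model never exceeds the independence model", {
  set.seed(51)
  for (rep in 1:1000) {
    v <- runif(sample(1:6, 1))
    expect_lte(combine_max(v), combine_independence(v) + 1e-12)
  }
  # equality iff at most one nonzero entry
  expect_equal(combine_max(c(0.3, 0, 0)), combine_independence(c(0.3, 0, 0)))
  expect_lt(combine_max(c(0.3, 0.2)), combine_independence(c(0.3, 0.2)))
})

test_that("equal wild-type and mutant posteriors give symmetric loss and gain", {
  p <- 0.6
  expect_equal(loss_given_stable(p, p), gain_given_stable(p, p))
})

test_that("near-one factors survive the log-space product path", {
  v <- loss_given_stable(0.9999999, 1e-12)
  expect_gt(v, 0.999999)
  expect_lte(v, 1)
})

test_that("an SOD1-like posterior pair yields near-certain marginal loss", {
  expect_gte(loss_marginal(0.99, 3.3e-3, 0.01), 0.98)
})

test_that("score_variant composes predictors, restrictions and combinations", {
  dat <- synth_motif_graphs(15, 15, size = 7, seed = 52)
  fitC <- fit_site_predictor(dat$envs, labeled = which(dat$y == 1), N = 3)
  env <- dat$envs[[1]]          # positive environment rooted at Cys

  ms <- score_variant(env, "G", models = list(Zn = fitC, Phos = fitC),
                      p_S = 0.2)
  expect_s3_class(ms, "mechanism_scores")
  pf <- ms$per_function
  expect_setequal(pf$fun, c("Zn", "Phos"))
  num_cols <- c("loss_stable", "loss_joint", "loss_marginal",
                "gain_stable", "gain_joint", "gain_marginal")
  expect_true(all(as.matrix(pf[, num_cols]) >= 0 &
                    as.matrix(pf[, num_cols]) <= 1))
  # Cys -> Gly: neither residue is phosphorylatable, so Phos is all-zero
  phos <- pf[pf$fun == "Phos", ]
  expect_equal(unname(unlist(phos[, num_cols])), rep(0, 6))
  expect_match(phos$reason, "not modifiable")
  # combined rows present for the category groups and the full set
  expect_true("all" %in% ms$combined$set)
  expect_true(all(ms$combined$loss_stable[ms$combined$model == "max"] <=
                    ms$combined$loss_stable[ms$combined$model == "independence"] + 1e-12))
})

test_that("a Tyr-to-Phe substitution cannot gain phosphorylation", {
  env <- make_env(c("Y", "A", "G"), rbind(c(1, 2), c(1, 3)))
  dat <- synth_motif_graphs(10, 10, size = 6, seed = 53)
  fit <- fit_site_predictor(dat$envs, labeled = which(dat$y == 1), N = 3)
  ms <- score_variant(env, "F", models = list(Phos = fit), p_S = 0.1)
  pf <- ms$per_function
  expect_equal(pf$gain_stable, 0)
  expect_equal(pf$gain_marginal, 0)
  # loss stays evaluable: tyrosine is modifiable
  expect_gte(pf$p_wt, 0)
})

test_that("mutant environments differ from wild type only at the root label", {
  env <- make_env(c("Y", "A", "G"), rbind(c(1, 2), c(1, 3)))
  mt <- mutate_root(env, "F")
  expect_equal(mt$graph$edges, env$graph$edges)
  expect_equal(mt$graph$vertices$label[-1], env$graph$vertices$label[-1])
  expect_equal(mt$graph$vertices$label[1], "F")
  # conservation class is inherited on the 40-symbol alphabet
  g40 <- split_alphabet_by_conservation(
    env$graph, c("X:1" = 0.1, "X:2" = 0.9, "X:3" = 0.9), pivot = 0.5)
  env40 <- structure(list(graph = g40, root = 1L, level = NA),
                     class = "rooted_env")
  mt40 <- mutate_root(env40, "F")
  expect_equal(mt40$graph$vertices$label[1], "f")  # stays non-conserved
})

test_that("mechanism scores serialize to a per-variant TSV", {
  env <- make_env(c("Y", "A", "G"), rbind(c(1, 2), c(1, 3)))
  dat <- synth_motif_graphs(8, 8, size = 6, seed = 54)
  fit <- fit_site_predictor(dat$envs, labeled = which(dat$y == 1), N = 3)
  ms <- score_variant(env, "F", models = list(Zn = fit), p_S = 0)
  path <- tempfile(fileext = ".tsv")
  write_mechanism_tsv(list(var1 = ms), path)
  back <- read.delim(path)
  expect_true("loss_stable" %in% names(back))
  expect_gte(nrow(back), 3)
})
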