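shaheen_mods <- modulator_vector(A = 1, SS = 1, D = 1, SB = 0)
ludwig_mods <- modulator_vector(A = 0.5, SS = 1, D = 0, B = 1, R = 1,
                                Pl = 0.5, SB = 1)

test_that("report-probability formulas reproduce the worked examples", {
  # perfectly tracking unbiased cohort: positive report is certain ...
  expect_equal(positive_report_probability(shaheen_mods, c("A", "SS", "D")), 1)
  # ... and a spurious positive is impossible
  expect_equal(negative_report_probability(shaheen_mods, c("A", "SS")), 0)
  # sponsor-biased trial with tracking average 1/2: P(ES=1|ind) = 0.675,
  # so the null result has probability 13/40 under the indicator
  m <- modulator_vector(A = 0.5, SS = 0.5, D = 0.5, B = 0.5, R = 0.5,
                        Pl = 0.5, SB = 1)
  expect_equal(positive_report_probability(m, c("A", "SS", "D", "B", "R", "Pl")),
               0.675)
  expect_equal(1 - 0.675, 13 / 40)
  # false-positive rate of the biased trial: 0.09, so P(ES=0|no ind)=0.91
  expect_equal(negative_report_probability(ludwig_mods,
                                           c("A", "SS", "B", "R", "Pl")),
               0.09)
  # floors and ceilings of the formulas
  worthless <- modulator_vector()
  expect_equal(positive_report_probability(worthless, c("A", "SS", "D")), 0.5)
  expect_equal(negative_report_probability(worthless, c("A", "SS")), 0.5)
})

test_that("formula preconditions are enforced", {
  expect_error(positive_report_probability(shaheen_mods, character(0)),
               "non-empty")
  expect_error(negative_report_probability(shaheen_mods, c("A", "SS", "D")),
               "duration")
  expect_error(positive_report_probability(shaheen_mods, "SBX"), "unknown")
  expect_error(modulator_vector(A = 1.3), "A out of \\[0,1\\]")
})

test_that("study designs target the indicators they can speak to", {
  expect_setequal(allowed_targets("case_control"), c("PD", "DR", "RoG"))
  expect_false("T" %in% allowed_targets("case_control"))
  expect_setequal(allowed_targets("cohort"), c("PD", "DR", "RoG", "T"))
  expect_true("Delta" %in% allowed_targets("rct"))
  expect_true(all(c("DR", "RoG") %in% allowed_targets("rct", multi_dose = TRUE)))
  expect_identical(allowed_targets("case_report"), "T")
  expect_true("Delta" %in% allowed_targets("case_report", delta_override = TRUE))
  expect_length(allowed_targets("basic_science"), 0L)

  expect_error(study_record("s", "case_control", "Delta", shaheen_mods, 1),
               "cannot speak to")
  expect_error(study_record("s", "cohort", c("PD", "DR"), shaheen_mods, 1),
               "exactly one statistical indicator")
})

test_that("attach_study builds the two-regime report CPT", {
  net <- build_causal_layer(causal_layer_config(prior_c = 0.01))
  shaheen <- study_record("shaheen", "cohort", c("DR", "T"), shaheen_mods, 1)
  net <- attach_study(net, shaheen)
  x <- net$cpts[["ES_shaheen"]]
  expect_equal(helper_p_true(x, DR = "true", T = "true"), 1)
  expect_equal(helper_p_true(x, DR = "true", T = "false"), 0)
  expect_equal(helper_p_true(x, DR = "false", T = "true"), 0)
  expect_equal(helper_p_true(x, DR = "false", T = "false"), 0)

  ludwig <- study_record("ludwig", "rct", "Delta", ludwig_mods, 0,
                         cpt_override = list(p_es0_given_true = 13 / 40,
                                             p_es0_given_false = 91 / 100))
  net <- attach_study(net, ludwig)
  y <- net$cpts[["ES_ludwig"]]
  expect_equal(helper_p_true(y, Delta = "true"), 1 - 13 / 40)
  expect_equal(helper_p_true(y, Delta = "false"), 1 - 91 / 100)
})

test_that("report probabilities are monotone in quality and bias", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  base <- modulator_vector(A = 0.5, SS = 0.5, D = 0.5, SB = 0.5)
  for (comp in c("A", "SS", "D")) {
    pos <- vapply(grid, function(v) {
      m <- base; m[[comp]] <- v
      positive_report_probability(m, c("A", "SS", "D"))
    }, numeric(1))
    expect_true(all(diff(pos) >= 0))
  }
  for (comp in c("A", "SS")) {
    neg <- vapply(grid, function(v) {
      m <- base; m[[comp]] <- v
      negative_report_probability(m, c("A", "SS"))
    }, numeric(1))
    expect_true(all(diff(neg) <= 0))
  }
  pos_sb <- vapply(grid, function(v) {
    m <- base; m$SB <- v
    positive_report_probability(m, c("A", "SS", "D"))
  }, numeric(1))
  neg_sb <- vapply(grid, function(v) {
    m <- base; m$SB <- v
    negative_report_probability(m, c("A", "SS"))
  }, numeric(1))
  expect_true(all(diff(pos_sb) <= 0))
  expect_true(all(diff(neg_sb) <= 0))
})

test_that("corner scenarios show tracking and bias pulling as expected", {
  good <- modulator_vector(A = 1, SS = 1, D = 1, SB = 0)
  good_biased <- modulator_vector(A = 1, SS = 1, D = 1, SB = 1)
  poor <- modulator_vector(A = 0.25, SS = 0.25, D = 0.25, SB = 0)
  poor_biased <- modulator_vector(A = 0.25, SS = 0.25, D = 0.25, SB = 1)
  tr_pos <- c("A", "SS", "D"); tr_neg <- c("A", "SS")
  p1 <- vapply(list(good, good_biased, poor, poor_biased),
               positive_report_probability, numeric(1), tracking = tr_pos)
  # a true signal is reported less often as tracking degrades or bias rises
  expect_true(p1[1] > p1[3] && p1[3] > p1[4])
  expect_true(p1[1] > p1[2])
  n1 <- vapply(list(good, good_biased, poor, poor_biased),
               negative_report_probability, numeric(1), tracking = tr_neg)
  # false positives rise with worse tracking but fall under bias
  expect_true(n1[3] > n1[1])
  expect_true(n1[2] <= n1[1] && n1[4] < n1[3])
})

test_that("hierarchical modulator mixtures collapse and average correctly", {
  s <- study_record("s", "cohort", c("DR", "T"),
                    modulator_vector(A = 0.5, SS = 1, D = 0.5, SB = 0), 1)
  point <- list(modulator_belief("A", 0.5, 1),
                modulator_belief("SS", 1, 1))
  expect_identical(marginalize_uncertain_modulator(point, s)$probs,
                   study_report_cpt(s)$probs)

  half <- modulator_belief("A", c(0, 1), c(0.5, 0.5))
  mixed <- marginalize_uncertain_modulator(list(half), s)
  s0 <- s; s0$modulators$A <- 0
  s1 <- s; s1$modulators$A <- 1
  expect_equal(mixed$probs,
               (study_report_cpt(s0)$probs + study_report_cpt(s1)$probs) / 2,
               tolerance = 1e-15)
  expect_error(modulator_belief("A", c(0, 1), c(0.6, 0.6)), "sum to 1")
})

test_that("a shared sponsorship-bias node updates on the group's reports", {
  net <- build_causal_layer(causal_layer_config(prior_c = 0.3))
  mods <- modulator_vector(A = 1, SS = 1, D = 0.5)
  s1 <- study_record("g1", "cohort", c("PD", "T"), mods, 0,
                     sponsor_group = "acme")
  s2 <- study_record("g2", "cohort", c("PD", "T"), mods, 0,
                     sponsor_group = "acme")
  belief <- modulator_belief("SB", c(0, 1), c(0.9, 0.1))
  net2 <- shared_bias_variable(net, "acme", belief, list(s1, s2))
  expect_identical(validate_network(net2), character(0))
  ev <- c(ES_g1 = "false", ES_g2 = "false")
  p_sb <- posterior(net2, ev, target = "SB_acme", state = "1")
  # two null results from one sponsor raise the bias suspicion above its
  # 0.1 prior; enumeration oracle agrees with variable elimination
  expect_gt(p_sb, 0.1)
  expect_equal(p_sb,
               brute_force_posterior(net2, ev, target = "SB_acme", state = "1"),
               tolerance = 1e-9)
  expect_equal(p_sb, helper_enum_posterior(net2, as.list(ev), "SB_acme", "1"),
               tolerance = 1e-9)

  # zero studies: network unchanged
  expect_identical(shared_bias_variable(net, "acme", belief, list()), net)
  # point-mass shared bias is the same as folding SB into the report CPT
  s3 <- study_record("solo", "cohort", c("PD", "T"),
                     modulator_vector(A = 1, SS = 1, D = 0.5, SB = 1), 0,
                     sponsor_group = "solo_grp")
  net_folded <- attach_study(net, s3)
  net_node <- shared_bias_variable(net, "solo_grp",
                                   modulator_belief("SB", 1, 1), list(s3))
  expect_equal(posterior(net_node, c(ES_solo = "false")),
               posterior(net_folded, c(ES_solo = "false")),
               tolerance = 1e-12)
  # mismatched group key is rejected
  expect_error(shared_bias_variable(net, "other", belief, list(s1)),
               "does not belong")
})
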