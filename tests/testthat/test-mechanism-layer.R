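case_mechanisms <- function() paracetamol_asthma_spec()$mechanisms

test_that("chain CPTs implement entailment, inconsistency and background rows", {
  specs <- case_mechanisms()
  m1 <- chain_cpts(specs[[1L]])
  # first link established regardless of the mechanism
  expect_equal(helper_p_true(m1[["mu_1_1"]], M1 = "true"), 1)
  expect_equal(helper_p_true(m1[["mu_1_1"]], M1 = "false"), 1)
  # middle link: entailed under M1, indifferent otherwise
  expect_equal(helper_p_true(m1[["mu_1_2"]], M1 = "true", mu_1_1 = "true"), 1)
  expect_equal(helper_p_true(m1[["mu_1_2"]], M1 = "false", mu_1_1 = "true"), 0.5)
  expect_equal(helper_p_true(m1[["mu_1_2"]], M1 = "false", mu_1_1 = "false"), 0.5)
  # final link: the full chain without the mechanism is inconsistent
  expect_equal(helper_p_true(m1[["mu_1_3"]], M1 = "false",
                             mu_1_1 = "true", mu_1_2 = "true"), 0)
  for (combo in list(c("false", "true"), c("true", "false"),
                     c("false", "false")))
    expect_equal(helper_p_true(m1[["mu_1_3"]], M1 = "false",
                               mu_1_1 = combo[1], mu_1_2 = combo[2]), 0.5)
  expect_equal(helper_p_true(m1[["mu_1_3"]], M1 = "true",
                             mu_1_1 = "true", mu_1_2 = "true"), 1)

  m2 <- chain_cpts(specs[[2L]])
  expect_equal(helper_p_true(m2[["mu_2_1"]], M2 = "true"), 1)
  expect_equal(helper_p_true(m2[["mu_2_1"]], M2 = "false"), 0.01)
  expect_equal(helper_p_true(m2[["mu_2_2"]], M2 = "true", mu_2_1 = "true"), 1)
  expect_equal(helper_p_true(m2[["mu_2_2"]], M2 = "false", mu_2_1 = "true"), 0)
  expect_equal(helper_p_true(m2[["mu_2_2"]], M2 = "false", mu_2_1 = "false"),
               0.5)
})

test_that("a single zero-background link is a perfect proxy for its mechanism", {
  spec <- mechanism_spec("Mx", 0.6, link_spec("mu_x", background = 0))
  x <- chain_cpts(spec)[["mu_x"]]
  expect_equal(helper_p_true(x, Mx = "true"), 1)
  expect_equal(helper_p_true(x, Mx = "false"), 0)
  net <- build_causal_layer(causal_layer_config(prior_c = 0.1))
  net <- build_mechanism_subnet(net, spec)
  expect_equal(posterior(net, c(mu_x = "true"), target = "Mx"), 1,
               tolerance = 1e-12)
})

test_that("the mechanism subnet of the case study assembles and validates", {
  net <- build_causal_layer(causal_layer_config(prior_c = 0.01))
  expect_identical(build_mechanism_subnet(net, list()), net)
  net2 <- build_mechanism_subnet(net, case_mechanisms())
  expect_identical(validate_network(net2), character(0))
  tags <- net2$tags
  expect_length(names(tags)[tags == "mechanism"], 2L)
  expect_length(names(tags)[tags == "sub-mechanism"], 5L)
  expect_length(names(tags)[tags == "report"], 6L)
  expect_equal(helper_p_true(net2$cpts[["M1"]], M = "true"), 0.7)
  expect_equal(helper_p_true(net2$cpts[["M1"]], M = "false"), 0)
  expect_equal(helper_p_true(net2$cpts[["M2"]], M = "true"), 0.8)
  # the full chain true forces the mechanism (enumeration)
  expect_equal(brute_force_posterior(net2, c(mu_1_1 = "true", mu_1_2 = "true",
                                             mu_1_3 = "true"),
                                     target = "M1"), 1, tolerance = 1e-12)
  # but partial chains keep positive probability without the mechanism
  expect_gt(brute_force_posterior(net2, c(mu_1_1 = "true", mu_1_2 = "true"),
                                  target = "M1", state = "false"), 0)
})

test_that("a shared link is true as soon as any parent mechanism holds", {
  specs <- list(
    mechanism_spec("Ma", 0.7, link_spec("L1", background = 0.5)),
    mechanism_spec("Mb", 0.8, link_spec("L1_ref", shared = "L1")))
  net <- build_causal_layer(causal_layer_config(prior_c = 0.5))
  net <- build_mechanism_subnet(net, specs)
  x <- net$cpts[["L1"]]
  expect_setequal(x$parents, c("Ma", "Mb"))
  expect_equal(helper_p_true(x, Ma = "true", Mb = "false"), 1)
  expect_equal(helper_p_true(x, Ma = "false", Mb = "true"), 1)
  expect_equal(helper_p_true(x, Ma = "false", Mb = "false"), 0.5)
  # enumeration: P(L1 | M) = 1 - (1-0.7)(1-0.8)(1-0.5)
  expect_equal(brute_force_posterior(net, c(M = "true"), target = "L1"),
               1 - 0.3 * 0.2 * 0.5, tolerance = 1e-12)
  expect_error(
    build_mechanism_subnet(net, mechanism_spec(
      "Mc", 0.5, link_spec("zz", shared = "nope"))),
    "missing link")
})

test_that("mechanism reports carry their Bayes-factor likelihood pairs", {
  net <- build_causal_layer(causal_layer_config(prior_c = 0.1))
  net <- build_mechanism_subnet(
    net, mechanism_spec("Mx", 0.7, link_spec("mu_a")), attach_reports = FALSE)
  net <- attach_mech_report(net, mech_report("mu_a", "confident"))
  net <- attach_mech_report(net, mech_report("mu_a", "cautious"))
  expect_equal(unname(net$cpts[["Rep_mu_a"]]$probs[, "true"]), c(0.09, 0.91))
  expect_equal(unname(net$cpts[["Rep_mu_a_2"]]$probs[, "true"]), c(0.25, 0.75))
  expect_error(mech_report("mu_a", "custom", likelihoods = c(0.5, 0.5)),
               "must exceed")
  expect_error(attach_mech_report(net, mech_report("nope", "confident")),
               "missing link")
})

test_that("mechanism evidence cannot raise the odds beyond 1/P(M|not C)", {
  set.seed(42)
  for (trial in 1:200) {
    prior <- runif(1, 0.01, 0.6)
    m_given_not_c <- runif(1, 0.2, 0.9)
    env <- random_mechanism_network(prior = prior,
                                    n_mech = sample(1:2, 1L),
                                    max_links = 2L,
                                    m_given_not_c = m_given_not_c)
    ev <- setNames(rep("true", length(env$reports)), env$reports)
    post <- posterior(env$net, ev)
    odds <- post / (1 - post)
    prior_odds <- prior / (1 - prior)
    expect_lte(odds, prior_odds / m_given_not_c + 1e-9)
  }
})

test_that("a positive confident report never lowers the causal posterior", {
  set.seed(43)
  for (trial in 1:25) {
    env <- random_mechanism_network(prior = runif(1, 0.05, 0.5),
                                    n_mech = 1L, max_links = 2L)
    links <- names(env$net$tags)[env$net$tags == "sub-mechanism"]
    before <- posterior(env$net)
    net2 <- attach_mech_report(env$net, mech_report(sample(links, 1L),
                                                    "confident"))
    new_rep <- setdiff(names(net2$tags)[net2$tags == "report"], env$reports)
    after <- posterior(net2, setNames("true", new_rep))
    expect_gte(after, before - 1e-12)
  }
})
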