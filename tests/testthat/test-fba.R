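test_that("model JSON schema round-trips and validation catches bad input", {
  mods <- toy_metabolic_models()
  path <- tempfile(fileext = ".json")
  write_model(mods$degrader, path)
  m2 <- load_model(path)
  expect_equal(dim(m2$S), dim(mods$degrader$S))
  expect_equal(fba_maximize(m2, "EX_A[u]")$value, 10, tolerance = 1e-9)
  # undeclared metabolite
  expect_error(metabolic_model(
    "bad", data.frame(id = "A[c]", compartment = "c"),
    list(list(id = "r1", metabolites = c(`B[c]` = 1), lb = 0, ub = 1,
              genes = character(0), organ = "x"))), "undeclared")
  # duplicate reaction id
  rx <- list(id = "r1", metabolites = c(`A[c]` = 1), lb = 0, ub = 1,
             genes = character(0), organ = "x")
  expect_error(metabolic_model("bad",
                               data.frame(id = "A[c]", compartment = "c"),
                               list(rx, rx)), "duplicate")
  # inverted bounds
  rx$lb <- 2
  expect_error(metabolic_model("bad",
                               data.frame(id = "A[c]", compartment = "c"),
                               list(rx)), "lb > ub")
})

test_that("flux maximization solves chains, detects unboundedness and infeasibility", {
  mods <- toy_metabolic_models()
  # linear chain: the uptake bound is the min cut
  res <- fba_maximize(apply_knockout(mods$degrader, "GENE_DEG"), "EX_A[u]")
  expect_equal(res$value, 10, tolerance = 1e-9)
  expect_equal(res$status, "optimal")
  # mass balance at the optimum
  expect_lt(max(abs(mods$degrader$S %*%
                      fba_maximize(mods$degrader, "EX_A[u]")$fluxes)), 1e-8)
  # uncapped cycle feeding the objective is unbounded
  cyc <- metabolic_model(
    "cycle", data.frame(id = c("A[c]", "B[c]"), compartment = "c"),
    list(list(id = "r_ab", metabolites = c(`A[c]` = -1, `B[c]` = 1),
              lb = 0, ub = Inf, genes = character(0), organ = "x"),
         list(id = "r_ba", metabolites = c(`B[c]` = -1, `A[c]` = 1),
              lb = 0, ub = Inf, genes = character(0), organ = "x"),
         list(id = "obj", metabolites = c(`A[c]` = 0), lb = 0, ub = Inf,
              genes = character(0), organ = "x")))
  expect_equal(fba_maximize(cyc, "obj")$status, "unbounded")
  # a forced lower bound that mass balance cannot satisfy
  inf <- metabolic_model(
    "inf", data.frame(id = "A[c]", compartment = "c"),
    list(list(id = "r_in", metabolites = c(`A[c]` = 1), lb = 0, ub = 1,
              genes = character(0), organ = "x"),
         list(id = "r_out", metabolites = c(`A[c]` = -1), lb = 5, ub = 6,
              genes = character(0), organ = "x")))
  expect_equal(fba_maximize(inf, "r_out")$status, "infeasible")
  expect_error(fba_maximize(cyc, "nope"), "unknown objective")
})

test_that("the LP core matches brute-force vertex enumeration on random models", {
  set.seed(13)
  for (i in 1:20) {
    n_met <- 2; n_rxn <- 5
    S <- matrix(sample(c(-1, 0, 1), n_met * n_rxn, TRUE), n_met, n_rxn)
    lb <- rep(0, n_rxn)
    ub <- runif(n_rxn, 1, 10)
    rxns <- lapply(seq_len(n_rxn), function(j) {
      sto <- S[, j]; names(sto) <- c("m1", "m2")
      list(id = paste0("r", j), metabolites = sto[sto != 0],
           lb = lb[j], ub = ub[j], genes = character(0), organ = "x")
    })
    rxns <- Filter(function(r) length(r$metabolites) > 0, rxns)
    if (length(rxns) < 2) next
    mod <- metabolic_model("rand",
                           data.frame(id = c("m1", "m2"),
                                      compartment = "c"), rxns)
    obj <- rxns[[1]]$id
    res <- fba_maximize(mod, obj)
    cvec <- as.numeric(names(mod$reactions) == obj)
    oracle <- lp_vertex_oracle(mod$S,
                               vapply(mod$reactions, `[[`, 0, "lb"),
                               vapply(mod$reactions, `[[`, 0, "ub"),
                               cvec)
    if (res$status == "optimal" && !is.null(oracle))
      expect_equal(res$value, oracle, tolerance = 1e-7)
  }
})

test_that("knockouts zero all associated reactions and refuse isozymes", {
  mods <- toy_metabolic_models()
  ko <- apply_knockout(mods$degrader, "GENE_DEG")
  expect_equal(ko$reactions$R_enzyme$lb, 0)
  expect_equal(ko$reactions$R_enzyme$ub, 0)
  # gene active in two organs: both reactions zeroed
  two <- metabolic_model(
    "two", data.frame(id = c("A[c]", "B[c]"), compartment = "c"),
    list(list(id = "in", metabolites = c(`A[c]` = 1), lb = 0, ub = 10,
              genes = character(0), organ = "gut"),
         list(id = "liver_rx", metabolites = c(`A[c]` = -1, `B[c]` = 1),
              lb = 0, ub = 5, genes = "G", organ = "liver"),
         list(id = "kidney_rx", metabolites = c(`A[c]` = -1, `B[c]` = 1),
              lb = 0, ub = 5, genes = "G", organ = "kidney"),
         list(id = "out", metabolites = c(`B[c]` = -1), lb = 0, ub = Inf,
              genes = character(0), organ = "gut")))
  ko2 <- apply_knockout(two, "G")
  expect_equal(ko2$reactions$liver_rx$ub, 0)
  expect_equal(ko2$reactions$kidney_rx$ub, 0)
  # isozyme sharing the reaction: refuse
  iso <- metabolic_model(
    "iso", data.frame(id = "A[c]", compartment = "c"),
    list(list(id = "r", metabolites = c(`A[c]` = 0), lb = 0, ub = 1,
              genes = c("G1", "G2"), organ = "x")))
  expect_error(apply_knockout(iso, "G1"), "isozyme")
  expect_error(apply_knockout(mods$degrader, "NOGENE"), "not present")
})

test_that("healthy reference fixes enzymes at their maximal activity", {
  mods <- toy_metabolic_models()
  h <- healthy_reference(mods$degrader, "GENE_DEG")
  expect_equal(h$reactions$R_enzyme$lb, 8, tolerance = 1e-9)
  expect_equal(h$reactions$R_enzyme$ub, 8, tolerance = 1e-9)
  h2 <- healthy_reference(mods$producer, "GENE_PROD")
  expect_equal(h2$reactions$R_enzyme$lb, 10, tolerance = 1e-9)
  expect_false(attr(h2, "zero_flux"))
  # sequential mode agrees on single-reaction genes
  h3 <- healthy_reference(mods$degrader, "GENE_DEG", mode = "sequential")
  expect_equal(h3$reactions$R_enzyme$lb, 8, tolerance = 1e-9)
  # a dead-end enzyme is fixed at zero and flagged
  dead <- metabolic_model(
    "dead", data.frame(id = c("A[c]", "B[c]"), compartment = "c"),
    list(list(id = "enz", metabolites = c(`A[c]` = -1, `B[c]` = 1),
              lb = 0, ub = 5, genes = "G", organ = "x")))
  hd <- healthy_reference(dead, "G")
  expect_true(attr(hd, "zero_flux"))
  expect_equal(hd$reactions$enz$ub, 0, tolerance = 1e-9)
})

test_that("the three fixtures reproduce the three knockout direction classes", {
  mods <- toy_metabolic_models()
  pd <- predict_direction(mods$degrader, "GENE_DEG", "A", "urine")
  expect_equal(pd$healthy_flux, 2, tolerance = 1e-9)
  expect_equal(pd$knockout_flux, 10, tolerance = 1e-9)
  expect_identical(pd$direction, "up")
  pd <- predict_direction(mods$producer, "GENE_PROD", "M", "urine")
  expect_equal(pd$healthy_flux, 10, tolerance = 1e-9)
  expect_equal(pd$knockout_flux, 0, tolerance = 1e-9)
  expect_identical(pd$direction, "down")
  pd <- predict_direction(mods$capacity_limited, "GENE_CAP", "M", "urine")
  expect_equal(pd$healthy_flux, 1, tolerance = 1e-9)
  expect_equal(pd$knockout_flux, 1, tolerance = 1e-9)
  expect_identical(pd$direction, "unchanged")
  pd <- predict_direction(mods$capacity_limited, "GENE_CAP", "M", "blood")
  expect_identical(pd$direction, "up")
  expect_gt(pd$knockout_flux, pd$healthy_flux)
})

test_that("zeroing a reaction cannot raise an objective without re-constraining", {
  mods <- toy_metabolic_models()
  for (nm in names(mods)) {
    m <- mods[[nm]]
    obj <- grep("^EX_", names(m$reactions), value = TRUE)[1]
    base <- fba_maximize(m, obj)$value
    ko <- fba_maximize(apply_knockout(m, ko_gene_for[[nm]]), obj)$value
    expect_lte(ko, base + 1e-9)
  }
})

test_that("exact binomial concordance tail matches enumeration", {
  ct <- concordance_binomial_test(rep("up", 9),
                                  c(rep("up", 8), "down"), 1 / 3)
  expect_equal(ct$n_match, 8)
  expect_equal(ct$p, 19 / 19683, tolerance = 1e-12)
  # degenerate nulls
  expect_equal(concordance_binomial_test(c("up", "up"), c("up", "up"),
                                         null_p = 1)$p, 1)
  expect_equal(concordance_binomial_test(rep("up", 5), rep("down", 5),
                                         0.5)$p, 1)
  expect_error(concordance_binomial_test("up", c("up", "down")),
               "length")
})
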