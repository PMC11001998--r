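# Curation rules: units, relations, duplicates, the spKi transform and
# target filtering.

test_that("unit standardization converts molar units and excludes the rest", {
  recs <- rbind(
    act_row("M1", value = 1,   units = "uM"),
    act_row("M2", value = 1,   units = "nM"),
    act_row("M3", value = 2,   units = "pM"),
    act_row("M4", value = 0.5, units = "mM"),
    act_row("M5", value = 1e-9, units = "M"),
    act_row("M6", value = 50,  units = "%"),
    act_row("M7", value = 10,  units = "ug.mL-1"))
  out <- standardize_units(recs)
  expect_equal(out$records$value, c(1000, 1, 0.002, 5e5, 1))
  expect_equal(unique(out$records$units), "nM")
  expect_equal(out$excluded$molecule_id, c("M6", "M7"))
  expect_equal(unique(out$excluded$reason), "unrecognized_units")
  # micro sign spelling converts like "uM"
  rec_mu <- act_row("M8", value = 3, units = paste0(intToUtf8(181), "M"))
  expect_equal(standardize_units(rec_mu)$records$value, 3000)
})

test_that("relation rules select measurements, upper bounds and inactives", {
  # censored-only: highest "<" value wins
  g <- rbind(act_row(relation = "<", value = 100),
             act_row(relation = "<", value = 500))
  res <- apply_relation_rules(g)
  expect_equal(res$outcome$ki_nM, 500)
  expect_equal(res$outcome$provenance, "upper_bound")

  # ">" only: inactive
  res2 <- apply_relation_rules(act_row(relation = ">", value = 10000))
  expect_true(res2$outcome$inactive)
  expect_equal(res2$outcome$provenance, "inactive_by_relation")

  # plain measurement
  res3 <- apply_relation_rules(act_row(relation = "=", value = 50))
  expect_equal(res3$outcome$ki_nM, 50)
  expect_equal(res3$outcome$provenance, "measured")

  # measured data wins over ">" and "<" records
  g4 <- rbind(act_row(relation = "=", value = 50),
              act_row(relation = ">", value = 10000),
              act_row(relation = "<", value = 20))
  res4 <- apply_relation_rules(g4)
  expect_equal(res4$outcome$ki_nM, 50)
  expect_match(res4$disposition[2], "superseded_by_measured")

  # exclusions: "=" with no value; no relation and no comment; "active"
  # comment without value
  g5 <- rbind(act_row(relation = "=", value = NA),
              act_row(relation = "", value = NA, comment = NA),
              act_row(relation = "", value = NA, comment = "Active"))
  res5 <- apply_relation_rules(g5)
  expect_null(res5$outcome)
  expect_true(all(startsWith(res5$disposition, "excluded:")))
})

test_that("duplicate resolution follows the order-of-magnitude recency rule", {
  # ratio 50 > 10: most recent wins
  expect_equal(resolve_duplicates(c(10, 500), c(2005, 2010)), 500)
  expect_equal(resolve_duplicates(c(500, 10), c(2010, 2005)), 500)
  # within one order of magnitude: geometric mean
  expect_equal(resolve_duplicates(c(10, 50), c(2005, 2010)),
               10^((1 + log10(50)) / 2))
  expect_equal(resolve_duplicates(c(10, 50), c(2005, 2010)), 22.36,
               tolerance = 1e-3)
  # single value unchanged; permutation invariance
  expect_equal(resolve_duplicates(7, 2000), 7)
  v <- c(12, 40, 90); y <- c(2001, 2002, 2003)
  p <- c(3, 1, 2)
  expect_equal(resolve_duplicates(v, y), resolve_duplicates(v[p], y[p]))
  # recency tie on the >10x branch: geometric mean of tied most-recent
  expect_equal(resolve_duplicates(c(10, 400, 900), c(2001, 2010, 2010)),
               sqrt(400 * 900))
})

test_that("spKi matches its branch definition and is monotone and continuous", {
  expect_equal(spki(20000), 0)
  expect_equal(spki(0.5), 1)
  expect_equal(spki(100), 0.5)
  expect_equal(spki(10), 0.75)
  expect_equal(spki(NA, inactive = TRUE), 0)
  # continuity at the branch points
  expect_equal(spki(1), 1)
  expect_equal(spki(1 + 1e-9), 1, tolerance = 1e-8)
  expect_equal(spki(10000), 0)
  expect_equal(spki(10000 - 1e-6), 0, tolerance = 1e-8)
  # monotone non-increasing over a log grid
  ki <- 10^seq(-2, 5, by = 0.1)
  expect_true(all(diff(spki(ki)) <= 1e-12))
  expect_error(spki(-1), "positive")
  # inverse on the linear branch
  s <- c(0.1, 0.5, 0.9)
  expect_equal(spki(spki_to_ki(s)), s)
})

test_that("target filtering drops sparse and flat targets with reasons", {
  cur <- rbind(
    data.frame(molecule_id = paste0("A", 1:39), target_id = "T_few",
               ki_nM = 10^seq(1, 3, length.out = 39),
               spki = spki(10^seq(1, 3, length.out = 39)),
               provenance = "measured"),
    data.frame(molecule_id = paste0("B", 1:100), target_id = "T_flat",
               ki_nM = NA, spki = 0, provenance = "inactive_by_relation"),
    data.frame(molecule_id = paste0("C", 1:40), target_id = "T_ok",
               ki_nM = 10^seq(0.5, 3.5, length.out = 40),
               spki = spki(10^seq(0.5, 3.5, length.out = 40)),
               provenance = "measured"))
  out <- filter_targets(cur)
  expect_equal(sort(unique(out$curated$target_id)), "T_ok")
  expect_equal(nrow(out$curated), 40)
  drop <- out$dropped_targets
  expect_equal(drop$reason[drop$target_id == "T_few"], "too_few_activities")
  expect_equal(drop$reason[drop$target_id == "T_flat"],
               "insufficient_variability")
  expect_error(filter_targets(cur[cur$target_id == "T_few", , drop = FALSE]),
               "survive")
})

test_that("full curation conserves records and is idempotent", {
  raw <- rbind(
    spread_target("T1", 45),
    act_row("D1", "T1", relation = "=", value = 10, year = 2005),
    act_row("D1", "T1", relation = "=", value = 50, year = 2010),
    act_row("E1", "T1", relation = "<", value = 200),
    act_row("F1", "T1", relation = ">", value = 10000),
    act_row("G1", "T1", relation = "=", value = 5, units = "%"),
    act_row("H1", "T1", type = "IC50", relation = "=", value = 5))
  out <- curate_activities(raw, min_activities = 40)
  # conservation: every record gets exactly one disposition
  expect_equal(nrow(out$record_report), nrow(raw))
  expect_true(all(startsWith(out$record_report$disposition, "used:") |
                    startsWith(out$record_report$disposition, "excluded:")))
  expect_equal(nrow(out$excluded) +
                 sum(startsWith(out$record_report$disposition, "used:")),
               nrow(raw))
  # the duplicate pair resolves to its geometric mean
  d1 <- out$curated[out$curated$molecule_id == "D1", ]
  expect_equal(d1$ki_nM, sqrt(10 * 50))
  # idempotence: re-curating the curated output reproduces spki exactly
  raw2 <- data.frame(
    molecule_id = out$curated$molecule_id, target_id = out$curated$target_id,
    activity_type = "Ki",
    relation = ifelse(out$curated$provenance == "inactive_by_relation",
                      ">", "="),
    value = ifelse(is.na(out$curated$ki_nM), 20000, out$curated$ki_nM),
    units = "nM", comment = NA, year = 2020, stringsAsFactors = FALSE)
  out2 <- curate_activities(raw2, min_activities = NULL)
  m <- match(paste(out$curated$molecule_id, out$curated$target_id),
             paste(out2$curated$molecule_id, out2$curated$target_id))
  expect_equal(out2$curated$spki[m], out$curated$spki)
})
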