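# Directed institution networks: edge semantics, psychiatrist
# aggregation, mode relationships.

two_patient_dose <- function(ids) {
  tibble::tibble(patient_id = ids,
                 annual_tablets = 400L, annual_ddd = 400,
                 group = factor("high", levels = c("low", "high")))
}

test_that("precedence edges capture any earlier institution per patient", {
  visits <- dplyr::bind_rows(
    toy_visit_seq("P1", 2008, c("A", "C")),
    toy_visit_seq("P2", 2008, c("B", "C"))
  )
  dose <- two_patient_dose(c("P1", "P2"))
  net <- build_network(visits, dose, "high", mode = "precedence",
                       index_year = 2008)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A C", "B C"))
  expect_equal(network_in_degree(net)[["C"]], 2L)
})

test_that("one patient at one institution produces no edges", {
  visits <- toy_visit_seq("P1", 2008, rep("A", 3))
  net <- build_network(visits, two_patient_dose("P1"), "high",
                       index_year = 2008)
  expect_equal(nrow(net$edges), 0)
  expect_equal(nrow(net$nodes), 1)
  expect_equal(network_density(net), 0)
})

test_that("A,B,A sequences give both directions in both modes", {
  visits <- toy_visit_seq("P1", 2008, c("A", "B", "A"))
  dose <- two_patient_dose("P1")
  for (mode in c("consecutive", "precedence")) {
    net <- build_network(visits, dose, "high", mode = mode,
                         index_year = 2008)
    e <- net$edges
    expect_setequal(paste(e$from, e$to), c("A B", "B A"))
    expect_equal(e$raw_weight, c(1L, 1L))
  }
})

test_that("precedence-mode weights count patients, not visit pairs", {
  # one patient commuting A,B,A,B: many ordered pairs but one patient
  visits <- toy_visit_seq("P1", 2008, c("A", "B", "A", "B"))
  dose <- two_patient_dose("P1")
  net_p <- build_network(visits, dose, "high", index_year = 2008)
  expect_equal(net_p$edges$raw_weight[net_p$edges$from == "A"], 1L)
  net_v <- build_network(visits, dose, "high", index_year = 2008,
                         weight_by = "pairs")
  # A visits at positions 1,3; B at 2,4: pairs A->B = {(1,2),(1,4),(3,4)}
  expect_equal(net_v$edges$raw_weight[net_v$edges$from == "A"], 3L)
  expect_true(all(net_v$edges$display_weight ==
                    log10(1 + net_v$edges$raw_weight)))
})

test_that("consecutive edges are a subset of precedence edges", {
  cfg <- small_config(n = 400, seed = 19)
  claims <- simulate_claims(cfg)
  sel <- select_cohort(claims$patients, claims$visits)
  dose <- classify_dose(claims$visits, sel)
  for (g in c("low", "high")) {
    cons <- build_network(claims$visits, dose, g, mode = "consecutive")
    prec <- build_network(claims$visits, dose, g, mode = "precedence")
    key <- function(e) paste(e$from, e$to)
    expect_true(all(key(cons$edges) %in% key(prec$edges)))
  }
})

test_that("same-day ties break deterministically by institution then record", {
  visits <- toy_visits(tibble::tibble(
    patient_id = "P1",
    visit_date = as.Date(c("2008-03-01", "2008-03-01")),
    institution_id = c("B", "A")
  ))
  net <- build_network(visits, two_patient_dose("P1"), "high",
                       index_year = 2008)
  # A sorts before B on the shared date, so the edge runs A -> B
  expect_equal(paste(net$edges$from, net$edges$to), "A B")
})

test_that("psychiatrist aggregation reroutes visits to one node and conserves visits", {
  visits <- dplyr::bind_rows(
    toy_visits(tibble::tibble(
      patient_id = "P1",
      visit_date = as.Date("2008-01-01") + 0:2,
      institution_id = c("A", "Y01", "B"),
      institution_level = c("clinic", "psychiatric_hospital", "clinic"),
      prescriber_is_psychiatrist = c(FALSE, TRUE, FALSE))),
    toy_visits(tibble::tibble(
      patient_id = "P2",
      visit_date = as.Date("2008-02-01") + 0:1,
      institution_id = c("C", "A"),
      prescriber_is_psychiatrist = c(TRUE, FALSE)))
  )
  dose <- two_patient_dose(c("P1", "P2"))
  off <- build_network(visits, dose, "high", index_year = 2008)
  agg <- build_network(visits, dose, "high", index_year = 2008,
                       psychiatrists = "aggregate")
  expect_equal(sum(agg$nodes$level == "psychiatrist_aggregate"), 1)
  expect_lte(nrow(agg$nodes), nrow(off$nodes))
  expect_equal(agg$n_visits, off$n_visits)
  # both psychiatrist visits (Y01 and the C clinic one) merged into PSY
  expect_true("PSY" %in% agg$nodes$node)
  expect_false(any(c("Y01", "C") %in% agg$nodes$node))
})

test_that("an empty dose group warns and returns an empty network", {
  visits <- toy_visit_seq("P1", 2008, c("A", "B"))
  dose <- two_patient_dose("P1")
  expect_warning(net <- build_network(visits, dose, "low", index_year = 2008),
                 "no patients")
  expect_equal(nrow(net$nodes), 0)
  expect_equal(network_density(net), 0)
})

test_that("county-only filtering drops out-of-county institutions", {
  visits <- toy_visits(tibble::tibble(
    patient_id = "P1",
    visit_date = as.Date("2008-01-01") + 0:2,
    institution_id = c("A", "X", "B"),
    in_county = c(TRUE, FALSE, TRUE)))
  dose <- two_patient_dose("P1")
  full <- build_network(visits, dose, "high", index_year = 2008)
  cty <- build_network(visits, dose, "high", index_year = 2008,
                       county_only = TRUE)
  expect_true("X" %in% full$nodes$node)
  expect_false("X" %in% cty$nodes$node)
})

test_that("tidy and glance expose edges and density", {
  visits <- toy_visit_seq("P1", 2008, c("A", "B", "C"))
  net <- build_network(visits, two_patient_dose("P1"), "high",
                       index_year = 2008)
  expect_equal(nrow(tidy(net)), nrow(net$edges))
  g <- glance(net)
  expect_equal(g$density, network_density(net))
  expect_equal(g$n_nodes, 3)
})
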