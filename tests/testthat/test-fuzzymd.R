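uniform_additive <- agg_choquet(L = 0, singleton = "ao1", alpha = 0)

test_that("FMD1 reduces to the classic power sum under the uniform additive measure", {
  expect_equal(fmd1(c(1, 2, 1), 1, 2, uniform_additive), 2)  # mean of 1,4,1
  # constant LOVIs: idempotency for any measure
  for (agg in list(agg_choquet(L = -1, singleton = "ao1", alpha = 0.3),
                   agg_choquet(L = 2, singleton = "ao2", alpha = 0.6)))
    expect_equal(fmd1(rep(3, 4), 2, 0.5, agg), 2 * 3^0.5, tolerance = 1e-12)
  # classic counterpart oracle: first Zagreb of P3 = 1 + 4 + 1 = 6
  deg <- vertex_degrees(fixture_molecules()$p3)
  expect_equal(classic_md1(deg, 1, 2), 6)
  expect_equal(fmd1(deg, 1, 2, uniform_additive), classic_md1(deg, 1, 2) / 3,
               tolerance = 1e-12)
  expect_error(fmd1(c(0, 1), 1, -0.5), "domain")
})

test_that("FMD4 aggregates ordered adjacent pairs (each edge twice)", {
  p3 <- fixture_molecules()$p3
  deg <- vertex_degrees(p3)
  # classic ordered-pair Randic-type sum: 4 ordered pairs, each 2^(-1/2)
  expect_equal(classic_md4(deg, adjacency(p3), 1, -0.5), 4 / sqrt(2),
               tolerance = 1e-10)
  expect_equal(classic_md4(deg, adjacency(p3), 1, -0.5), 2 * sqrt(2),
               tolerance = 1e-10)
  # additive-uniform reduction: classic / W with W = #ordered adjacent pairs
  expect_equal(fmd4(deg, p3, 1, -0.5, uniform_additive),
               classic_md4(deg, adjacency(p3), 1, -0.5) / 4, tolerance = 1e-12)
  # single-edge molecule: both multiset copies equal => idempotency
  pair <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.5, 0, 0)),
                   rbind(c(1, 2, 1)))
  dp <- vertex_degrees(pair)
  expect_equal(fmd4(dp, pair, 1.5, 2, agg_choquet(L = 3, singleton = "ao1",
                                                  alpha = 0.8)),
               1.5 * (1 * 1)^2, tolerance = 1e-12)
  lone <- molecule("C", cbind(0, 0, 0))
  expect_error(fmd4(1, lone, 1, 1), "no-edges")
})

test_that("FMD5 runs over all ordered pairs", {
  p3 <- fixture_molecules()$p3
  deg <- vertex_degrees(p3)
  # classic hand enumeration of the 6 ordered pairs: 2(1*2 + 1*1 + 2*1) = 10
  expect_equal(classic_md5(deg, 1, 1), 10)
  expect_equal(fmd5(deg, 1, 1, uniform_additive), 10 / 6, tolerance = 1e-12)
  # n = 2: single repeated value => idempotent
  expect_equal(fmd5(c(2, 3), 1, 1, agg_choquet(L = 0.5, singleton = "ao1",
                                               alpha = 0.7)),
               6, tolerance = 1e-12)
})

test_that("FMD6 fuses powered LOVIs within each fragment", {
  p3 <- fixture_molecules()$p3
  deg <- vertex_degrees(p3)
  frags1 <- path_fragments(p3, 1)
  # m = 0 fragments: Choquet of a singleton is the value itself
  expect_equal(fmd6(deg, path_fragments(p3, 0), 1, 2, uniform_additive),
               sum(deg^2), tolerance = 1e-12)
  # uniform additive measure: per-fragment mean of the powered LOVIs
  # (hand: fragments {1,2} and {2,3}, each mean(1, 2^-0.5) = 0.853553)
  expect_equal(fmd6(deg, frags1, 1, -0.5, uniform_additive),
               2 * mean(c(1, 1 / sqrt(2))), tolerance = 1e-12)
  expect_equal(fmd6(deg, frags1, 1, -0.5, uniform_additive),
               sum(vapply(frags1, function(fr) mean(deg[fr]^-0.5), numeric(1))),
               tolerance = 1e-12)
  # the classic product-form counterpart (Kier-Hall 1-chi) by hand: 1.4142
  expect_equal(classic_md6(deg, frags1, 1, -0.5), sqrt(2), tolerance = 1e-10)
  # fragment of identical LOVIs contributes c^lambda' regardless of measure
  expect_equal(fmd6(c(2, 2, 2), list(c(1, 2), c(2, 3)), 1, 3,
                    agg_choquet(L = 4, singleton = "ao2", alpha = 0.9)),
               2 * 8, tolerance = 1e-12)
  expect_warning(v <- fmd6(deg, list(), 1, 1), "empty")
  expect_equal(v, 0)
})

test_that("FMD7 restricts FMD4 to a fragment", {
  hexa <- fixture_molecules()$hexagon
  deg <- vertex_degrees(hexa)
  agg <- agg_choquet(L = 0.25, singleton = "ao1", alpha = 0.2)
  expect_equal(fmd7(deg, hexa, 1:6, 1, 1, agg), fmd4(deg, hexa, 1, 1, agg),
               tolerance = 1e-12)
  # fragment spanning one edge: idempotent value
  expect_equal(fmd7(deg, hexa, c(1, 2), 1, -0.5, agg), (2 * 2)^-0.5,
               tolerance = 1e-12)
  # atoms 1 and 4 are not adjacent in the ring
  expect_error(fmd7(deg, hexa, c(1, 4), 1, 1, agg), "no-edges")
})

test_that("named fuzzy indices bind the documented parameters", {
  hexa <- fixture_molecules()$hexagon
  agg <- agg_choquet(L = 0.5, singleton = "ao1", alpha = 0.8)
  # Balaban-like alpha' = B / (C + 1) = 6 / 2 = 3 on the hexagon
  expect_equal(fuzzy_balaban(hexa, agg),
               fmd4(vertex_degrees(hexa), hexa, 3, -0.5, agg), tolerance = 1e-12)
  p3 <- fixture_molecules()$p3
  expect_equal(fuzzy_first_zagreb(p3, uniform_additive), 2, tolerance = 1e-12)
  expect_equal(fuzzy_second_zagreb(p3, uniform_additive),
               classic_md4(vertex_degrees(p3), adjacency(p3), 1, 1) / 4,
               tolerance = 1e-12)
  expect_equal(fuzzy_randic(p3, uniform_additive), 2 * sqrt(2) / 4,
               tolerance = 1e-12)
  # Kier-Hall binding: per-fragment Choquet of the powered degrees
  expect_equal(fuzzy_kier_hall(p3, 1, uniform_additive),
               2 * mean(c(1, 1 / sqrt(2))), tolerance = 1e-12)
  expect_equal(fuzzy_autocorrelation(p3, c(1, 2), uniform_additive),
               fmd7(vertex_degrees(p3), p3, c(1, 2), 1, 1, uniform_additive))
})

test_that("fuzzy descriptors are bounded by their contribution multiset", {
  set.seed(73)
  mol <- random_molecule(6, seed = 8)
  deg <- vertex_degrees(mol)
  for (rep in 1:20) {
    agg <- agg_choquet(L = runif(1, -1, 4),
                       singleton = sample(c("ao1", "ao2"), 1),
                       alpha = runif(1))
    t1 <- deg^1.5
    expect_gte(fmd1(deg, 1, 1.5, agg), min(t1) - 1e-12)
    expect_lte(fmd1(deg, 1, 1.5, agg), max(t1) + 1e-12)
  }
})

test_that("descriptor values are continuous in L across the branch boundary", {
  deg <- vertex_degrees(fixture_molecules()$star)
  val <- function(L) fmd1(deg, 1, 2, agg_choquet(L = L, singleton = "ao1",
                                                 alpha = 0.3))
  # both-sided check at L = 0 and near L = -1
  expect_equal(val(-1e-8), val(0), tolerance = 1e-6)
  expect_equal(val(1e-8), val(0), tolerance = 1e-6)
  expect_equal(val(-1), val(-1 + 1e-8), tolerance = 1e-6)
  grid <- seq(-1, 1, by = 0.05)
  vals <- vapply(grid, val, numeric(1))
  expect_true(all(abs(diff(vals)) < 0.25 * (max(vals) - min(vals)) + 1e-9))
})

test_that("the global geometric descriptor is FMD1 on the pipeline LOVIs", {
  pair <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(1.54, 0, 0)),
                   rbind(c(1, 2, 1)))
  # full hand trace at n = 2: both LOVIs equal e1 + e2 = 5.10, so every
  # normalized measure returns that constant
  expect_equal(fuzzy_qubils_global(pair, qubils_config(),
                                   agg_choquet(L = 0.5, singleton = "ao1",
                                               alpha = 0.8)),
               5.10, tolerance = 1e-12)
  # additive measure: AO-weighted mean of the LOVIs
  mol <- random_molecule(5, seed = 4)
  lov <- qubils_lovis(mol, qubils_config())
  dens <- as.numeric(ao1_densities(lov, 0.4))
  expect_equal(fuzzy_qubils_global(mol, qubils_config(),
                                   agg_choquet(L = 0, singleton = "ao1",
                                               alpha = 0.4)),
               sum(dens * lov), tolerance = 1e-10)
})

test_that("descriptor matrices are deterministic with per-cell failure reasons", {
  fx <- fixture_molecules()
  configs <- list(
    descriptor_config("zagreb1", "fmd1", 1, 2, agg = uniform_additive),
    descriptor_config("randic", "fmd4", 1, -0.5,
                      agg = agg_choquet(L = 0.5, singleton = "ao1", alpha = 0.2)),
    descriptor_config("kh1", "fmd6", 1, -0.5, m = 1L, agg = uniform_additive),
    descriptor_config("geom", "qubils_global", lovis = qubils_config(),
                      agg = agg_choquet(L = -0.5, singleton = "ao2", alpha = 0.5)))
  mols <- list(fx$p3, fx$star, fx$hexagon)
  dm <- compute_matrix(mols, configs)
  expect_equal(dim(dm), c(3L, 4L))
  expect_true(all(is.finite(dm)))
  # identical molecules => identical rows; permuted input => permuted rows
  dm2 <- compute_matrix(list(fx$hexagon, fx$p3, fx$star), configs)
  expect_equal(unname(dm2[c(2, 3, 1), ]), unname(dm), ignore_attr = TRUE)
  # a single-atom molecule cannot form pairs: NA with a reason, batch survives
  # (its empty fragment list also warns, by design)
  lone <- molecule("C", cbind(0, 0, 0), name = "lone")
  dm3 <- suppressWarnings(compute_matrix(list(fx$p3, lone), configs))
  expect_true(is.na(dm3["lone", "randic"]))
  expect_match(attr(dm3, "reasons")["lone", "randic"], "no-edges")
  expect_false(anyNA(dm3["p3", ]))
  # CSV serialization writes NA:<reason> cells
  path <- tempfile(fileext = ".csv")
  write_descriptor_matrix(dm3, path)
  lines <- readLines(path)
  expect_equal(length(lines), 3)
  expect_match(lines[1], "^molecule,zagreb1,randic,kh1,geom$")
  expect_match(lines[3], "NA:no-edges")
  expect_error(compute_matrix(mols, configs[c(1, 1)]), "duplicate")
})

test_that("YAML configurations and presets load into descriptor configs", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "descriptors:",
    "- label: test1",
    "  family: fmd1",
    "  alpha_prime: 1.0",
    "  lambda_prime: 2.0",
    "  lovis: {source: degree}",
    "  aggregator:",
    "    type: choquet",
    "    measure: {family: lmdelta, L: 0.0}",
    "    singleton: {type: ao1, alpha: 0.0}"), yml)
  cfgs <- read_config_yaml(yml)
  expect_length(cfgs, 1)
  expect_equal(cfgs[[1]]$label, "test1")
  dm <- compute_matrix(list(fixture_molecules()$p3), cfgs)
  expect_equal(unname(dm[1, 1]), 2, tolerance = 1e-12)  # uniform-additive Zagreb
  presets <- preset_configs()
  expect_length(presets, 42)
  Ls <- vapply(presets, function(cf) cf$agg$L, numeric(1))
  expect_setequal(unique(Ls), c(-0.75, -0.5, -0.25, 0.25, 0.5, 0.75))
})

test_that("the command-line interface computes and reports in-process", {
  sdf <- tempfile(fileext = ".sdf")
  write_sdf(fixture_molecules()[c("p3", "hexagon")], sdf)
  out <- tempfile(fileext = ".csv")
  suppressMessages(dm <- choqmd_main(c("compute", "--sdf", sdf, "--out", out)))
  expect_true(file.exists(out))
  expect_equal(dim(dm), c(2L, 42L))
  rep <- choqmd_main(c("paper-stats", "--out", tempfile()))
  expect_equal(rep$wilcoxon$p_two_sided, 0.0078125)
  expect_error(choqmd_main(character(0)), "usage")
})
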