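test_that("self-returning walk counts match known values and the enumeration oracle", {
  # toluene has only even rings: every odd-order count vanishes
  expect_equal(srw_count(parse_structure("Cc1ccccc1"), 9), 0)
  # 3-atom path: closed 2-walks = 2 * edge count
  expect_equal(srw_count(carbon_graph(rbind(c(1, 2), c(2, 3))), 2), 4)
  # plain 5-cycle: closed 9-walks, frozen from exhaustive enumeration
  c5 <- carbon_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)))
  expect_equal(srw_count(c5, 9), 360)
  expect_equal(oracle_srw(c5, 9), 360)
  expect_error(srw_count(c5, 0), "k must be")
})

test_that("walk and path counts equal brute-force enumeration on random graphs", {
  graphs <- generate_random_graphs(40, size_range = c(4, 8),
                                   odd_ring_probability = 0.4, seed = 101)
  for (g in graphs) {
    expect_equal(srw_count(g, 4), oracle_srw(g, 4))
    expect_equal(multiple_path_count(g, 4), oracle_pipc(g, 4))
  }
  # odd order on five-ring graphs, where it is nonzero
  ringy <- generate_random_graphs(10, c(5, 7), odd_ring_probability = 1,
                                  seed = 7)
  for (g in ringy) {
    v <- srw_count(g, 9)
    expect_gt(v, 0)
    expect_equal(v, oracle_srw(g, 9))
  }
})

test_that("odd-order walk counts vanish on bipartite graphs", {
  trees <- generate_random_graphs(25, size_range = c(2, 8),
                                  odd_ring_probability = 0, seed = 5)
  for (g in trees) {
    expect_equal(srw_count(g, 3), 0)
    expect_equal(srw_count(g, 9), 0)
  }
  c6 <- carbon_graph(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1)))
  expect_equal(srw_count(c6, 9), 0)
})

test_that("ramification index counts degree excess over 2", {
  solv <- solvent_data()
  expect_equal(ram_index(parse_structure(solv$smiles[1])), 3)   # N-cyclohexyl-pyrrolidinone
  expect_equal(ram_index(parse_structure("Cc1ccccc1")), 1)      # toluene
  expect_equal(ram_index(parse_structure("OCCOCCOCCO")), 0)     # unbranched chain
  # on trees: equals a direct degree scan
  for (g in generate_random_graphs(15, c(3, 8), 0, seed = 11)) {
    deg <- graph_degrees(g)
    expect_equal(ram_index(g), sum(deg[deg > 2] - 2L))
  }
})

test_that("valence degrees follow the Kier-Hall conventions", {
  ace <- parse_structure("CC(=O)C")
  dv <- valence_degrees(ace)
  expect_equal(sort(dv), c(1, 1, 4, 6))          # two CH3, carbonyl C, O
  clp <- parse_structure("Oc1ccccc1Cl")
  expect_equal(valence_degrees(clp)[clp$elements == "Cl"], 7 / 9,
               tolerance = 1e-12)
  expect_error(valence_degrees(parse_structure("C")), "non-positive")
})

test_that("average valence connectivity matches printed and closed-form values", {
  expect_equal(round(chi0v_average(parse_structure("NC=O")), 3), 0.521)
  expect_equal(round(chi0v_average(parse_structure("CC(C)=O")), 3), 0.727)
  expect_equal(round(chi0v_average(parse_structure("Oc1ccccc1Cl")), 3), 0.611)
  expect_equal(chi0v_average(parse_structure("CC")), 1)
  # closed forms: carbon path (2 + (n-2)/sqrt(2))/n, carbon star on 5 atoms
  p5 <- carbon_graph(cbind(1:4, 2:5))
  expect_equal(chi0v_average(p5), (2 + 3 / sqrt(2)) / 5)
  star <- carbon_graph(cbind(1, 2:5))
  expect_equal(chi0v_average(star), (4 + 1 / sqrt(4)) / 5)
  # invariant under atom relabeling
  g1 <- molecular_graph(c("C", "O", "C"), rbind(c(1, 2, 1), c(2, 3, 1)))
  g2 <- molecular_graph(c("O", "C", "C"), rbind(c(2, 1, 1), c(1, 3, 1)))
  expect_equal(chi0v_average(g1), chi0v_average(g2))
})

test_that("bond-order weighted path counts reproduce the Kekule spot values", {
  expect_equal(multiple_path_count(parse_structure("Cc1ccccc1"), 5), 44)
  expect_equal(multiple_path_count(parse_structure("OCc1ccccc1"), 5), 50)
  # a single-bond path of exactly k edges holds one path of weight 1
  expect_equal(multiple_path_count(carbon_graph(cbind(1:5, 2:6)), 5), 1)
  expect_error(multiple_path_count(parse_structure("CC"), 0), "k must be")
})

test_that("mass autocorrelation is zero beyond diameter and counts single pairs", {
  p3 <- carbon_graph(rbind(c(1, 2), c(2, 3)))
  expect_equal(ats_autocorrelation(p3, 6), 0)               # diameter 2 < 6
  p7 <- carbon_graph(cbind(1:6, 2:7))
  expect_equal(ats_autocorrelation(p7, 6), 12.011^2)        # one pair at lag 6
  expect_equal(ats_autocorrelation(p7, 6, weight = "scaled-mass"), 1)
  expect_equal(ats_autocorrelation(p7, 6, dialect = "log1p"),
               log1p(12.011^2))
  expect_error(ats_autocorrelation(p7, 6, dialect = "nope"))
  # include-H reaches farther than the heavy-atom graph
  expect_gt(ats_autocorrelation(p3, 4, dialect = "include-H"), 0)
})

test_that("descriptor matrix assembly merges computed and supplied columns", {
  solv <- solvent_data()[1:4, ]
  dz <- setNames(c(2.2, -0.1, 1.3, 0.5), solv$id)
  m <- build_descriptor_matrix(solv, supplied = list(DipoleZ = dz))
  expect_s3_class(m, "descriptor_matrix")
  expect_equal(nrow(m), 4L)
  prov <- attr(m, "provenance")
  expect_equal(unname(prov["DipoleZ"]), "supplied")
  expect_true(all(prov[setdiff(names(prov), "DipoleZ")] == "computed"))

  empty <- build_descriptor_matrix(solv[0, ])
  expect_equal(nrow(empty), 0L)

  expect_error(build_descriptor_matrix(solv, supplied = list(DipoleZ = dz[-2])),
               "missing id 2")
})

test_that("reference verification flags only unexplained cells", {
  solv <- solvent_data()
  ref <- reference_descriptors()
  comp <- build_descriptor_matrix(solv)
  chk <- verify_against_reference(
    comp, ref,
    tolerance = c(X0Av = 0.002, SRW09 = 0.5, Ram = 0.5, piPC05 = 0.5,
                  ATS6m = 0.01),
    known_discrepancies = cntdisp:::.known_discrepancies(ref))
  expect_equal(chk$n_flagged, 0L)
  expect_true("DipoleZ" %in% names(ref))

  identicalchk <- verify_against_reference(ref, ref)
  expect_equal(sum(identicalchk$cells$flag), 0L)

  extra <- ref
  extra$Bogus <- seq_len(nrow(ref))
  chk2 <- verify_against_reference(extra, ref)
  expect_equal(chk2$skipped, "Bogus")

  expect_error(verify_against_reference(comp[-1, ], ref), "ids differ")
})

test_that("no autocorrelation dialect is asserted against the printed column", {
  solv <- solvent_data()
  ref <- reference_descriptors()
  graphs <- lapply(solv$smiles, parse_structure)
  rep <- ats_dialect_report(graphs, ref$ATS6m, k = 6)
  expect_equal(nrow(rep), 6L)
  expect_true(all(rep$mean_abs_diff > 0))        # none reproduces the table
  # zero-valued printed cells are matched by the raw-sum dialect exactly
  raw <- vapply(graphs, ats_autocorrelation, numeric(1), k = 6)
  expect_true(all(raw[ref$ATS6m == 0 & ref$id %in%
                        c(11, 16, 17, 19, 22, 24, 25, 28)] == 0))
})
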