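test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- default_sim_config(seed = 7, n_genes = 200, n_cells_source = 500,
                            n_cells_target = 400)
  a <- generate_pair(cfg)
  b <- generate_pair(cfg)
  expect_identical(a$source$counts, b$source$counts)
  expect_identical(a$target$counts, b$target$counts)
  expect_identical(a$source$labels, b$source$labels)
  expect_identical(a$orthologs, b$orthologs)
  expect_identical(a$truth$p_source, b$truth$p_source)

  # a different seed changes the draw
  c <- generate_pair(default_sim_config(seed = 8, n_genes = 200,
                                        n_cells_source = 500,
                                        n_cells_target = 400))
  expect_false(identical(a$source$counts, c$source$counts))
})

test_that("with zero divergence both species share per-class gene frequencies", {
  tree <- bone_marrow_tree()
  ab <- c(Erythroblast = 0.22, Neutrophil = 0.14, Myelocyte = 0.12,
          Monocyte = 0.10, Myeloblast = 0.08, Monoblast = 0.07,
          ProB = 0.06, PreB = 0.06, Tlymphocyte = 0.05, Basophil = 0.02,
          Megakaryocyte = 0.02, Pericyte = 0.02, Endothelial = 0.02,
          HSPC = 0.02)
  classes <- names(ab)
  cfg <- sim_config(n_genes = 300, classes = classes,
                    tree = tree, abundance_source = ab, abundance_target = ab,
                    divergence = 0, heterogeneity = 0,
                    n_cells_source = 20000, n_cells_target = 20000, seed = 21)
  pair <- generate_pair(cfg)
  bs <- binarize(pair$source$counts)
  bt <- binarize(pair$target$counts)
  for (k in classes) {
    fs <- colMeans(bs[pair$source$labels == k, , drop = FALSE])
    ft <- colMeans(bt[pair$target$labels == k, , drop = FALSE])
    expect_lt(sqrt(mean((fs - ft)^2)), 0.02)
  }
  # and both match the generating truth matrices
  expect_lt(sqrt(mean((colMeans(bs[pair$source$labels == "Erythroblast", ]) -
                         pair$truth$p_source["Erythroblast", ])^2)), 0.02)
})

test_that("sparsity calibration hits the requested zero fraction", {
  cfg <- default_sim_config(seed = 5, n_genes = 1000, n_cells_source = 2000,
                            n_cells_target = 400, base_expr_prob = 0.12)
  cal <- calibrate_sparsity(cfg, 0.94)
  # an over-dense program makes the target unreachable, and says so
  expect_error(calibrate_sparsity(default_sim_config(program_size = 100,
                                                     n_genes = 400), 0.94),
               "unreachable")
  pair <- generate_pair(cal)
  realized <- mean(binarize(pair$source$counts) == 0)
  expect_equal(realized, 0.94, tolerance = 0.011)
})

test_that("realized zero fraction decreases monotonically in base_expr_prob", {
  zf <- vapply(c(0.02, 0.05, 0.1, 0.2), function(b) {
    pair <- generate_pair(default_sim_config(
      seed = 9, n_genes = 250, n_cells_source = 2000, n_cells_target = 300,
      base_expr_prob = b))
    mean(pair$source$counts == 0)
  }, numeric(1))
  expect_true(all(diff(zf) < 0))
})

test_that("tree-adjacent classes share more program genes than distant ones", {
  for (seed in c(2, 13)) {
    pair <- generate_pair(default_sim_config(seed = seed, n_genes = 300,
                                             n_cells_source = 800,
                                             n_cells_target = 600))
    prog <- pair$truth$programs
    tree <- pair$tree
    jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
    cls <- names(prog)
    adj <- dist2 <- numeric(0)
    for (i in seq_along(cls)) {
      for (j in seq_len(i - 1)) {
        d <- lineage_distance(tree, cls[i], cls[j])
        jc <- jac(prog[[cls[i]]], prog[[cls[j]]])
        if (d == 1) adj <- c(adj, jc) else if (d >= 2) dist2 <- c(dist2, jc)
      }
    }
    expect_gt(mean(adj), mean(dist2))
  }
})

test_that("per-class cell counts follow the abundance multinomial", {
  pair <- generate_pair(default_sim_config(seed = 31, n_genes = 100,
                                           n_cells_source = 6000,
                                           n_cells_target = 300))
  ab <- pair$config$abundance_source
  obs <- table(factor(pair$source$labels, levels = names(ab)))
  p <- suppressWarnings(stats::chisq.test(obs, p = ab)$p.value)
  expect_gt(p, 0.001)
})

test_that("species-exclusive classes appear only in their species", {
  pair <- small_pair(seed = 4)
  expect_false(any(pair$source$labels == "ImmatureB"))
  expect_false(any(pair$target$labels %in% c("Megakaryocyte", "Endothelial")))
  expect_true(all(c("Megakaryocyte", "Endothelial") %in% pair$source$labels))
  expect_true("ImmatureB" %in% pair$target$labels)
})

test_that("truth matrices are probabilities", {
  pair <- small_pair(seed = 6)
  expect_true(all(pair$truth$p_source >= 0 & pair$truth$p_source <= 1))
  expect_true(all(pair$truth$p_target >= 0 & pair$truth$p_target <= 1))
})

test_that("invalid configurations are rejected", {
  tree <- bone_marrow_tree()
  ab <- c(A = 0.5, B = 0.5)
  expect_error(sim_config(classes = c("A", "B"), tree = tree,
                          abundance_source = ab, abundance_target = ab),
               "tree does not cover")
  ab_bad <- c(HSPC = 0.6, Erythroblast = 0.5)
  expect_error(
    default_sim_config(abundance_source = ab_bad),
    "configuration error")
  # zero cells drawn for a present class
  expect_error(
    generate_pair(default_sim_config(seed = 1, n_genes = 200,
                                     n_cells_source = 12,
                                     n_cells_target = 400)),
    "zero cells")
})

test_that("datasets round-trip through the on-disk layout", {
  pair <- generate_pair(default_sim_config(seed = 3, n_genes = 120,
                                           n_cells_source = 300,
                                           n_cells_target = 250))
  dir <- file.path(tempdir(), "synthio-roundtrip")
  manifest <- write_dataset(pair, dir)
  expect_length(manifest, 10)
  expect_true(all(file.exists(file.path(dir, manifest))))

  src <- read_species_dataset(dir, "source")
  expect_equal(unname(src$counts), unname(pair$source$counts))
  expect_identical(src$labels, pair$source$labels)
  expect_identical(src$gene_names, pair$source$gene_names)
  tgt <- read_species_dataset(dir, "target")
  expect_equal(unname(tgt$counts), unname(pair$target$counts))

  orth <- read_orthologs(file.path(dir, "orthologs.tsv"))
  expect_identical(orth, pair$orthologs)
  tree <- read_tree_json(file.path(dir, "tree.json"))
  expect_identical(tree$nodes, pair$tree$nodes)

  expect_error(write_dataset(pair, "/proc/definitely-unwritable/x"),
               "definitely-unwritable")
})
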