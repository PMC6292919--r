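test_that("network thresholding keeps equality and drops strictly-lower weights", {
  # S = 0.2 exactly: two 5-gene sets sharing one gene
  pa <- pathway("X", "PA", "a", sprintf("A%d", 1:5))
  pb <- pathway("X", "PB", "b", c("A1", sprintf("B%d", 1:4)))
  net <- build_network(list(pa, pb), min_weight = 0.2)
  expect_equal(nrow(network_edges(net)), 1L)
  expect_equal(network_edges(net)$weight, 0.2)

  # S = 0.19 < 0.2: removed
  pc <- pathway("X", "PC", "c", sprintf("C%d", 1:100))
  pd <- pathway("X", "PD", "d", c(sprintf("C%d", 1:19), sprintf("D%d", 1:81)))
  net2 <- build_network(list(pc, pd), min_weight = 0.2)
  expect_equal(nrow(network_edges(net2)), 0L)

  # min_weight = 0 keeps every positive-overlap pair but stores no zero edges
  pe <- pathway("X", "PE", "e", c("Z1", "Z2"))
  net3 <- build_network(list(pa, pb, pe), min_weight = 0)
  el <- network_edges(net3)
  expect_equal(nrow(el), 1L)
  expect_true(all(el$weight > 0))

  expect_error(build_network(list(pa)), class = "pathmapr_validation_error")
})

test_that("edge weights equal the overlap coefficient of the endpoint gene sets", {
  withr::with_seed(51, {
    db <- random_db("N", n = 8L, pool = 30L)
    net <- build_network(unname(db$pathways), min_weight = 0.1)
    el <- network_edges(net)
    for (r in seq_len(nrow(el))) {
      p <- net$pathways[[el$source[r]]]
      q <- net$pathways[[el$target[r]]]
      expect_equal(el$weight[r], oracle_overlap(p$genes, q$genes))
      expect_gte(el$weight[r], 0.1)
    }
  })
})

test_that("modules are connected components of size >= 2; isolated nodes unassigned", {
  ps <- list(
    pathway("X", "P1", "a", c("A", "B")),
    pathway("X", "P2", "b", c("A", "B", "C")),
    pathway("X", "P3", "c", c("D", "E")),
    pathway("X", "P4", "d", c("D", "E", "F")),
    pathway("X", "P5", "e", c("Z1", "Z2"))
  )
  net <- build_network(ps, min_weight = 0.2)
  part <- detect_modules(net)
  expect_length(part$modules, 2L)
  expect_setequal(part$modules[["M1"]], c("X:P1", "X:P2"))
  expect_setequal(part$modules[["M2"]], c("X:P3", "X:P4"))
  expect_identical(part$unassigned, "X:P5")

  # partition covers all nodes exactly once
  covered <- c(unlist(part$modules, use.names = FALSE), part$unassigned)
  expect_setequal(covered, pathway_key(ps))
  expect_equal(anyDuplicated(covered), 0L)
})

test_that("components agree with a union-find oracle on random networks", {
  withr::with_seed(52, {
    for (rep in 1:20) {
      db <- random_db("R", n = sample(5:9, 1), pool = 25L)
      thr <- sample(c(0.2, 0.3, 0.5), 1)
      net <- build_network(unname(db$pathways), min_weight = thr)
      part <- detect_modules(net)
      el <- network_edges(net)
      comps <- oracle_components(pathway_key(unname(db$pathways)),
                                 el$source, el$target)
      expected_modules <- Filter(function(g) length(g) >= 2, comps)
      got <- unname(lapply(part$modules, sort))
      expect_setequal(
        vapply(got, paste, character(1), collapse = ","),
        vapply(lapply(expected_modules, sort), paste, character(1), collapse = ",")
      )
      # component count is non-decreasing as the threshold rises
      thresholds <- c(0, 0.25, 0.5, 0.75, 1)
      ncomp <- vapply(thresholds, function(w) {
        p <- detect_modules(build_network(unname(db$pathways), min_weight = w))
        length(p$modules) + length(p$unassigned)
      }, numeric(1))
      expect_true(all(diff(ncomp) >= 0))
      # edge count is non-increasing as the threshold rises
      nedge <- vapply(thresholds, function(w) {
        nrow(network_edges(build_network(unname(db$pathways), min_weight = w)))
      }, numeric(1))
      expect_true(all(diff(nedge) <= 0))
    }
  })
})

test_that("module core genes are the intersection of member gene sets", {
  core <- sprintf("CORE%d", 1:5)
  withr::with_seed(53, {
    ps <- lapply(1:4, function(i) {
      pathway("X", sprintf("P%d", i), "p",
              c(core, sprintf("EXTRA%d_%d", i, 1:sample(2:5, 1))))
    })
  })
  expect_identical(module_core_genes(ps), sort(core))

  same <- list(pathway("X", "P1", "a", c("A", "B")),
               pathway("X", "P2", "b", c("A", "B")))
  expect_identical(module_core_genes(same), c("A", "B"))

  disjoint <- list(pathway("X", "P1", "a", c("A")),
                   pathway("X", "P2", "b", c("B")))
  expect_identical(module_core_genes(disjoint), character())
})

test_that("overlap regions partition the union of gene sets", {
  a <- pathway("X", "A", "a", c("G1", "G2"))
  b <- pathway("X", "B", "b", c("G3", "G4"))
  r <- overlap_regions(list(a, b))
  expect_equal(r[["X:A"]], 2L)
  expect_equal(r[["X:B"]], 2L)
  expect_false("X:A&X:B" %in% names(r))

  # nested sets
  small <- pathway("X", "S", "s", c("G1", "G2"))
  big <- pathway("X", "L", "l", c("G1", "G2", "G3"))
  r2 <- overlap_regions(list(small, big))
  expect_equal(r2[["X:S&X:L"]], 2L)
  expect_equal(r2[["X:L"]], 1L)

  withr::with_seed(54, {
    ps <- lapply(1:3, function(i) {
      pathway("X", sprintf("P%d", i), "p", random_gene_set(15, 3, 10))
    })
    r3 <- overlap_regions(ps)
    expect_equal(sum(r3),
                 length(unique(unlist(lapply(ps, `[[`, "genes")))))
    # brute-force per-gene signature assignment
    for (g in unique(unlist(lapply(ps, `[[`, "genes")))) {
      sig <- paste(pathway_key(ps)[vapply(ps, function(p) g %in% p$genes,
                                          logical(1))], collapse = "&")
      expect_true(sig %in% names(r3))
    }
  })

  many <- lapply(1:7, function(i) pathway("X", sprintf("P%d", i), "p", "G1"))
  expect_error(overlap_regions(many), class = "pathmapr_limit_error")
})

test_that("dendrogram merges identical pathways at 0 and disjoint ones at 1", {
  same <- list(pathway("X", "P1", "a", c("A", "B")),
               pathway("X", "P2", "b", c("A", "B")))
  d <- cluster_dendrogram(same)
  expect_equal(d$height, 0)

  disjoint <- list(pathway("X", "P1", "a", c("A", "B")),
                   pathway("X", "P2", "b", c("C", "D")))
  expect_equal(cluster_dendrogram(disjoint)$height, 1)
})

test_that("dendrogram heights match stats::hclust average linkage", {
  withr::with_seed(55, {
    for (rep in 1:15) {
      db <- random_db("H", n = 8L, pool = 40L, min_size = 4L, max_size = 15L)
      ps <- unname(db$pathways)
      dend <- cluster_dendrogram(ps)
      expect_true(!is.unsorted(dend$height))

      keys <- sort(pathway_key(ps))
      dm <- matrix(0, 8, 8, dimnames = list(keys, keys))
      for (i in 1:8) {
        for (j in 1:8) {
          pi <- ps[[match(keys[i], pathway_key(ps))]]
          pj <- ps[[match(keys[j], pathway_key(ps))]]
          dm[i, j] <- 1 - oracle_overlap(pi$genes, pj$genes)
        }
      }
      ref <- stats::hclust(stats::as.dist(dm), method = "average")
      expect_equal(sort(dend$height), sort(ref$height), tolerance = 1e-12)
      # cophenetic matrices agree, so the tree topology matches too
      expect_equal(
        as.matrix(stats::cophenetic(dend))[keys, keys],
        as.matrix(stats::cophenetic(ref))[keys, keys],
        tolerance = 1e-12
      )
    }
  })
})

test_that("unassigned pathways join the module of their nearest dendrogram leaf", {
  ps <- list(
    pathway("X", "P1", "a", c("A", "B", "C")),
    pathway("X", "P2", "b", c("A", "B", "C", "D")),
    pathway("X", "P3", "c", c("Q", "R", "S")),
    pathway("X", "P4", "d", c("Q", "R", "S", "T")),
    # shares a little with the P1/P2 group only
    pathway("X", "P5", "e", c("A", "Z1", "Z2", "Z3", "Z4", "Z5"))
  )
  net <- build_network(ps, min_weight = 0.9)
  part <- detect_modules(net)
  expect_true("X:P5" %in% part$unassigned)
  dend <- cluster_dendrogram(ps)
  full <- assign_to_closest_module(part, dend)
  expect_length(full$unassigned, 0L)
  m_of <- function(key) names(which(vapply(full$modules, function(m) key %in% m,
                                           logical(1))))
  expect_identical(m_of("X:P5"), m_of("X:P1"))

  # identity when nothing is unassigned
  part2 <- detect_modules(build_network(ps[1:4], min_weight = 0.5))
  expect_identical(assign_to_closest_module(part2, cluster_dendrogram(ps[1:4])),
                   part2)

  # all unassigned stays unchanged (no module to join)
  part3 <- detect_modules(build_network(ps, min_weight = 1.1))
  expect_length(part3$modules, 0L)
  expect_identical(assign_to_closest_module(part3, dend), part3)
})

test_that("newick export round-trips through ape with matching heights", {
  withr::with_seed(56, {
    db <- random_db("T", n = 6L)
  })
  dend <- cluster_dendrogram(unname(db$pathways))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(dend, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label,
                  gsub(":", "-", pathway_key(unname(db$pathways)), fixed = TRUE))
  expect_equal(max(ape::node.depth.edgelength(phy)), max(dend$height) / 2,
               tolerance = 1e-8)
})
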