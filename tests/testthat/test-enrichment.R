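# Neighborhood statistics: nh_sum against BFS, the permutation enrichment
# test, pairwise z-scores, and group composition ratios.

ring_cells <- function(n, types, seed = 1) {
  set.seed(seed)
  data.frame(cell_id = paste0("c", seq_len(n)),
             x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
             cell_type = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("nh_sum counts k-layer neighbors by type with a conserved all column", {
  # isolated node: all-zero row
  cells <- data.frame(cell_id = c("a", "b", "c"),
                      x_um = 1:3, y_um = 1, cell_type = c("T", "T", "U"))
  g <- igraph::make_empty_graph(3, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = c("a", "b", "c"))
  g <- igraph::add_edges(g, c(1, 2))
  Y <- nh_sum(cells, g, k = 1)
  expect_equal(unname(Y["c", ]), c(0, 0, 0))
  expect_equal(unname(Y["a", "T"]), 1)
  # conservation and BFS equality on random graphs
  set.seed(88)
  for (rep in 1:6) {
    n <- 80L
    cells <- ring_cells(n, c("A", "B", "C"), seed = rep)
    g <- igraph::sample_gnp(n, 0.04)
    g <- igraph::set_vertex_attr(g, "name", value = cells$cell_id)
    edges <- igraph::as_edgelist(g, names = FALSE)
    for (k in c(1, 3)) {
      Y <- nh_sum(cells, g, k = k)
      expect_equal(Y[, "all"],
                   rowSums(Y[, setdiff(colnames(Y), "all"), drop = FALSE]))
      for (i in sample(n, 10L)) {
        nb <- oracle_bfs(edges, n, i, k)
        expect_equal(unname(Y[cells$cell_id[i], "all"]), length(nb))
        expect_equal(unname(Y[cells$cell_id[i], "A"]),
                     sum(cells$cell_type[nb] == "A"))
      }
    }
  }
})

# star scene: selected hubs, each with its own private partners; hubs are
# never in each other's k = 1 neighborhoods
star_graph <- function(n_hub, spokes_per_hub) {
  n <- n_hub * (spokes_per_hub + 1L)
  ids <- paste0("c", seq_len(n))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  edges <- integer(0)
  for (h in seq_len(n_hub)) {
    hub <- (h - 1L) * (spokes_per_hub + 1L) + 1L
    for (s in seq_len(spokes_per_hub)) {
      edges <- c(edges, hub, hub + s)
    }
  }
  igraph::add_edges(g, edges)
}

test_that("enrichment is 1 with p 1 when every non-selected cell is the target", {
  g <- star_graph(5, 4)
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  hubs <- ids[seq(1, n, by = 5)]
  cells <- data.frame(cell_id = ids, x_um = 0, y_um = 0,
                      cell_type = ifelse(ids %in% hubs, "DC", "T"),
                      stringsAsFactors = FALSE)
  res <- permutation_enrichment(cells, g, hubs, "T", k = 1, n_perm = 99,
                                seed = 1)
  expect_equal(res$score, 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_density, 1)
  expect_equal(res$baseline, 1)
})

test_that("planted enrichment reaches the minimal p-value with score above 1", {
  g <- star_graph(6, 4)
  ids <- igraph::V(g)$name
  hubs <- ids[seq(1, length(ids), by = 5)]
  # targets only in selected neighborhoods; elsewhere background type
  cells <- data.frame(cell_id = ids, x_um = 0, y_um = 0,
                      cell_type = "bg", stringsAsFactors = FALSE)
  cells$cell_type[cells$cell_id %in% hubs] <- "DC"
  spokes <- setdiff(ids, hubs)
  cells$cell_type[cells$cell_id %in% spokes[1:12]] <- "target"
  # put the 12 target cells inside hubs 1-3; add isolated background cells
  # carrying the baseline
  iso <- data.frame(cell_id = paste0("x", 1:20), x_um = 0, y_um = 0,
                    cell_type = c("target", rep("bg", 19)),
                    stringsAsFactors = FALSE)
  all_cells <- rbind(cells, iso)
  g2 <- igraph::add_vertices(g, 20, name = iso$cell_id)
  res <- permutation_enrichment(all_cells, g2, hubs, "target", k = 1,
                                n_perm = 1000, seed = 7)
  expect_gt(res$score, 1)
  expect_equal(res$p_value, 1 / 1001)
})

test_that("permutation enrichment is deterministic under a fixed seed and stable under relabeling", {
  set.seed(10)
  cells <- ring_cells(120, c("DC", "T", "A", "B"), seed = 3)
  g <- delaunay_graph(cells)
  sel <- cells$cell_id[cells$cell_type == "DC"][1:10]
  r1 <- permutation_enrichment(cells, g, sel, "T", n_perm = 200, seed = 5)
  r2 <- permutation_enrichment(cells, g, sel, "T", n_perm = 200, seed = 5)
  expect_identical(r1$null_scores, r2$null_scores)
  expect_identical(r1$p_value, r2$p_value)
  r3 <- permutation_enrichment(cells, g, sel, "T", n_perm = 200, seed = 6)
  expect_false(identical(r1$null_scores, r3$null_scores))
  # relabeling non-target, non-selected types does not change the result
  cells2 <- cells
  cells2$cell_type[cells2$cell_type == "A"] <- "Z"
  r4 <- permutation_enrichment(cells2, g, sel, "T", n_perm = 200, seed = 5)
  expect_equal(r1$score, r4$score)
  expect_equal(r1$null_scores, r4$null_scores)
})

test_that("enrichment errors are informative", {
  cells <- ring_cells(30, c("DC", "T"), seed = 2)
  g <- delaunay_graph(cells)
  expect_error(permutation_enrichment(cells, g, character(0), "T"), "non-empty")
  expect_error(permutation_enrichment(cells, g, "nope", "T"), "unknown ids")
  expect_error(permutation_enrichment(cells, g, cells$cell_id[1], "Qq"),
               "not present")
  expect_error(nh_sum(cells, g, k = -1), "k")
})

test_that("pairwise enrichment signs follow spatial mixing and segregation", {
  # interleaved lattice of A and B
  n <- 14L
  grid <- expand.grid(x = seq_len(n), y = seq_len(n))
  inter <- data.frame(cell_id = paste0("c", seq_len(nrow(grid))),
                      x_um = grid$x * 10, y_um = grid$y * 10,
                      cell_type = ifelse((grid$x + grid$y) %% 2 == 0, "A", "B"),
                      stringsAsFactors = FALSE)
  g <- delaunay_graph(inter)
  z <- pairwise_enrichment(inter, g, n_perm = 200, seed = 3)
  expect_gt(z["A", "B"], 2)
  # segregated blocks
  seg <- inter
  seg$cell_type <- ifelse(grid$x <= n / 2, "A", "B")
  zs <- pairwise_enrichment(seg, delaunay_graph(seg), n_perm = 200, seed = 3)
  expect_lt(zs["A", "B"], -2)
  # same-label edges excluded: diagonal of the observed matrix is zero
  expect_true(all(diag(attr(z, "observed")) == 0))
})

test_that("group_composition reproduces hand-computed ratios and the pseudocount guard", {
  # 6-cell toy neighborhood matrix, 3 groups x 4 types
  Y <- rbind(c(2, 1, 0, 1), c(1, 1, 0, 0), c(0, 3, 0, 1),
             c(1, 0, 0, 2), c(2, 2, 0, 0), c(0, 1, 0, 3))
  Y <- cbind(Y, rowSums(Y))
  colnames(Y) <- c("T1", "T2", "T3", "T4", "all")
  rownames(Y) <- paste0("c", 1:6)
  groups <- setNames(c("g1", "g1", "g2", "g2", "g3", "g3"), rownames(Y))
  eps <- 0.001
  out <- group_composition(Y, groups, pseudocount = eps)
  # hand computation for g1 / T1: in-group sums 3 of 6; complement 3 of 15
  expect_equal(out["g1", "T1"], ((3 + eps) / (6 + eps)) / ((3 + eps) / (15 + eps)))
  # g2 / T4: in-group 3 of 7; complement 4 of 14
  expect_equal(out["g2", "T4"], ((3 + eps) / (7 + eps)) / ((4 + eps) / (14 + eps)))
  # all-zero type stays finite thanks to the pseudocount
  expect_true(all(is.finite(out[, "T3"])))
  # a group with identical composition to the rest sits at ratio ~ 1
  Yc <- matrix(rep(c(2, 1, 1), each = 8), 8, 3)
  Yc <- cbind(Yc, rowSums(Yc))
  colnames(Yc) <- c("A", "B", "C", "all")
  rownames(Yc) <- paste0("r", 1:8)
  gc <- setNames(rep(c("u", "v"), each = 4), rownames(Yc))
  outc <- group_composition(Yc, gc)
  expect_true(all(abs(outc - 1) < 1e-2))
  # errors
  expect_error(group_composition(Y, setNames("g1", "nope")), "row names")
  expect_error(group_composition(Y[, 1:4], groups), "all")
})

test_that("renormalization centres one type's ratios across groups", {
  Y <- rbind(c(5, 1, 6), c(1, 5, 6), c(3, 3, 6), c(2, 2, 4))
  colnames(Y) <- c("T1", "T2", "all")
  rownames(Y) <- paste0("c", 1:4)
  groups <- setNames(c("a", "a", "b", "b"), rownames(Y))
  out <- group_composition(Y, groups, normalize_type = "T2")
  expect_equal(mean(out[, "T2"]), 1)
})
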