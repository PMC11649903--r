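# axis atoms far outside the sphere so they never interfere
axis_frame <- function(extra = NULL, axis_elem = "C") {
  at <- data.frame(atom = c("X1", "X2", "Y1", "Y2"), resid = "DUM",
                   resno = 1:4, chain = "A", elem = axis_elem,
                   x = -30, y = c(-30, 30, -30, 30),
                   z = c(-30, -30, 30, 30), stringsAsFactors = FALSE)
  if (!is.null(extra)) at <- rbind(at, extra)
  md_frame(at)        # sphere center: (-30, 0, 0)
}

axis_spec <- function(...) {
  pocket_spec(c("A:1:X1", "A:2:X2"), c("A:3:Y1", "A:4:Y2"), ...)
}

test_that("empty sphere volume matches the analytic ball and the count oracle", {
  pv <- pocket_volume(axis_frame(), axis_spec(hull_prune = FALSE))
  want_n <- oracle_sphere_count(12, 0.5)
  expect_equal(pv$n_points, want_n)
  expect_equal(pv$volume, want_n * 0.125)
  # within one grid-shell discretization band of (4/3) pi 12^3
  analytic <- 4 / 3 * pi * 12^3
  shell <- 4 * pi * 12^2 * 0.5
  expect_lt(abs(pv$volume - analytic), shell)
})

test_that("a fully packed sphere has zero pocket volume", {
  r <- 4
  ks <- seq(-r, r, by = 1)
  g <- expand.grid(x = ks, y = ks, z = ks)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= (r + 1)^2, ]
  extra <- data.frame(atom = paste0("P", seq_len(nrow(g))), resid = "PCK",
                      resno = 100L + seq_len(nrow(g)), chain = "B",
                      elem = "C", x = g$x - 30, y = g$y, z = g$z)
  pv <- pocket_volume(axis_frame(extra),
                      axis_spec(radius = r, hull_prune = FALSE))
  expect_equal(pv$n_points, 0)
  expect_equal(pv$volume, 0)
})

test_that("a single atom removes exactly the grid points inside its exclusion ball", {
  center <- c(-30, 0, 0)
  atom_at <- center + c(0.2, 0.1, -0.3)
  extra <- data.frame(atom = "P1", resid = "PCK", resno = 100L,
                      chain = "B", elem = "C", x = atom_at[1],
                      y = atom_at[2], z = atom_at[3])
  pv <- pocket_volume(axis_frame(extra), axis_spec(hull_prune = FALSE))
  # brute-force per-point check on the same anchored grid
  kmax <- floor(12 / 0.5)
  offs <- 0.5 * seq(-kmax, kmax)
  g <- as.matrix(expand.grid(offs, offs, offs))
  g <- g[rowSums(g^2) <= 12^2 + 1e-9, , drop = FALSE]
  g <- sweep(g, 2, center, "+")
  d2 <- (g[, 1] - atom_at[1])^2 + (g[, 2] - atom_at[2])^2 +
    (g[, 3] - atom_at[3])^2
  expect_equal(pv$n_points, sum(d2 >= 1.09^2 - 1e-9))
  expect_gt(pv$n_removed_atoms, 0)
})

test_that("points exactly at the exclusion cutoff are retained", {
  center <- c(-30, 0, 0)
  # atom exactly 1.09 A from the grid point at the sphere center
  extra <- data.frame(atom = "P1", resid = "PCK", resno = 100L,
                      chain = "B", elem = "C", x = center[1] + 1.09,
                      y = 0, z = 0)
  pv <- pocket_volume(axis_frame(extra), axis_spec(hull_prune = FALSE))
  expect_true(any(rowSums(sweep(pv$grid, 2, center)^2) < 1e-18))
  # hydrogens are not heavy atoms and never delete points
  extra_h <- data.frame(atom = "H1", resid = "PCK", resno = 101L,
                        chain = "B", elem = "H", x = center[1], y = 0,
                        z = 0)
  pv_h <- pocket_volume(axis_frame(extra_h), axis_spec(hull_prune = FALSE))
  expect_equal(pv_h$n_points, oracle_sphere_count(12, 0.5))
})

test_that("convex-hull pruning keeps only points inside the heavy-atom hull", {
  # cube of corner atoms around the center: hull is the cube itself
  half <- 4
  corners <- expand.grid(x = c(-half, half), y = c(-half, half),
                         z = c(-half, half))
  extra <- data.frame(atom = paste0("P", 1:8), resid = "PCK",
                      resno = 100L + 1:8, chain = "B", elem = "C",
                      x = corners$x - 30, y = corners$y, z = corners$z)
  # axis atoms as hydrogens: only the cube corners are heavy, so the
  # hull is exactly the cube
  pv <- pocket_volume(axis_frame(extra, axis_elem = "H"),
                      axis_spec(radius = 10))
  inside_cube <- abs(sweep(pv$grid, 2, c(-30, 0, 0))) <= half + 1e-9
  expect_true(all(inside_cube))
  # every surviving point is clear of the corner atoms AND in the cube;
  # count against a brute-force reconstruction
  kmax <- floor(10 / 0.5)
  offs <- 0.5 * seq(-kmax, kmax)
  g <- as.matrix(expand.grid(offs, offs, offs))
  g <- g[rowSums(g^2) <= 10^2 + 1e-9, , drop = FALSE]
  in_cube <- apply(abs(g) <= half + 1e-9, 1, all)
  corner_m <- as.matrix(corners)
  clear <- vapply(seq_len(nrow(g)), function(i)
    min(sqrt(colSums((t(corner_m) - g[i, ])^2))) >= 1.09 - 1e-9,
    logical(1))
  expect_equal(pv$n_points, sum(in_cube & clear))
  expect_error(pocket_volume(
    md_frame(data.frame(atom = c("X1", "X2", "Y1", "Y2"), resid = "DUM",
                        resno = 1:4, chain = "A",
                        elem = "H", x = -30, y = c(-30, 30, -30, 30),
                        z = c(-30, -30, 30, 30))),
    axis_spec()), "heavy atom")
})

test_that("pocket volume is exactly invariant under translation", {
  set.seed(77)
  extra <- data.frame(atom = paste0("P", 1:12), resid = "PCK",
                      resno = 100L + 1:12, chain = "B", elem = "C",
                      x = runif(12, -36, -24), y = runif(12, -6, 6),
                      z = runif(12, -6, 6))
  fr <- axis_frame(extra)
  pv0 <- pocket_volume(fr, axis_spec(hull_prune = FALSE))
  shifted <- fr
  shift <- c(11.3, -7.9, 3.14)
  shifted$x <- shifted$x + shift[1]
  shifted$y <- shifted$y + shift[2]
  shifted$z <- shifted$z + shift[3]
  pv1 <- pocket_volume(md_frame(shifted), axis_spec(hull_prune = FALSE))
  expect_equal(pv1$n_points, pv0$n_points)
  expect_equal(pv1$volume, pv0$volume)
})

test_that("pocket specifications validate their geometry", {
  expect_error(pocket_spec(c("a", "b"), c("c", "d"), spacing = 13),
               "smaller than the radius")
  expect_error(pocket_spec(c("a", "b"), c("c", "d"), exclusion = -1))
  expect_error(pocket_spec("a", c("c", "d")))
})
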