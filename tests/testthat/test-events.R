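test_that("region labelling follows 8-connectivity with exact barycenters", {
  expect_equal(nrow(label_regions(matrix(FALSE, 5, 5))), 0L)

  # diagonal neighbours form one region
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- m[3, 3] <- TRUE
  expect_equal(nrow(label_regions(m)), 1L)

  # plus-shaped blob centred at (10, 10)
  m <- matrix(FALSE, 20, 20)
  m[10, 10] <- m[9, 10] <- m[11, 10] <- m[10, 9] <- m[10, 11] <- TRUE
  regs <- label_regions(m)
  expect_equal(nrow(regs), 1L)
  expect_equal(regs$x, 10)
  expect_equal(regs$y, 10)
  expect_equal(regs$size, 5L)
})

test_that("labelling matches an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (rep in 1:10) {
    m <- matrix(runif(400) < 0.3, 20, 20)
    regs <- label_regions(m)
    idx <- which(m)
    if (length(idx) == 0) {
      expect_equal(nrow(regs), 0L)
      next
    }
    ys <- (idx - 1) %% 20 + 1
    xs <- (idx - 1) %/% 20 + 1
    adj <- which(outer(ys, ys, function(a, b) abs(a - b) <= 1) &
                   outer(xs, xs, function(a, b) abs(a - b) <= 1),
                 arr.ind = TRUE)
    g <- igraph::graph_from_edgelist(apply(adj, 2, identity),
                                     directed = FALSE)
    expect_equal(nrow(regs), igraph::components(g)$no)
  }
})

test_that("polarity classification is antisymmetric with the documented tie", {
  a <- matrix(0, 8, 8)
  b <- a
  b[4, 4] <- 5
  px <- which(b > 0)
  expect_equal(classify_polarity(px, a, b), "appearing")
  expect_equal(classify_polarity(px, b, a), "vanishing")
  expect_equal(classify_polarity(px, a, a), "appearing")  # exact-zero tie
})

test_that("mean-shift merges duplicates and keeps lone events", {
  ev1 <- data.frame(id = 1L, pair = 3L, x = 20, y = 20,
                    polarity = "appearing", size = 5L, balance = 0)
  cl1 <- meanshift_cluster(ev1)
  expect_equal(nrow(cl1$clusters), 1L)
  expect_false(cl1$clusters$discarded)

  # two same-polarity events 1 px / 1 frame apart collapse to the midpoint
  ev2 <- data.frame(id = 1:2, pair = c(3L, 4L), x = c(20, 21),
                    y = c(20, 20), polarity = "appearing", size = 5L,
                    balance = 0)
  cl2 <- meanshift_cluster(ev2, h_s = 5, h_t = 2)
  expect_equal(nrow(cl2$clusters), 1L)
  expect_equal(cl2$clusters$x, 20.5, tolerance = 0.01)
  expect_equal(cl2$clusters$pair, 3.5, tolerance = 0.01)

  # opposite polarities in the same neighbourhood are a motion artifact
  ev3 <- data.frame(id = 1:2, pair = c(3L, 4L), x = c(20, 22),
                    y = c(20, 20), polarity = c("appearing", "vanishing"),
                    size = 5L, balance = 0)
  cl3 <- meanshift_cluster(ev3)
  expect_true(all(cl3$clusters$discarded))

  # a dipole region is discarded on its own
  ev4 <- data.frame(id = 1L, pair = 3L, x = 20, y = 20,
                    polarity = "appearing", size = 10L, balance = 0.9)
  expect_true(meanshift_cluster(ev4)$clusters$discarded)
  expect_false(meanshift_cluster(ev4, motion_filter = FALSE)$clusters$discarded)
})

test_that("clustering is permutation invariant and contraction-idempotent", {
  set.seed(5)
  ev <- data.frame(id = 1:12, pair = rep(c(2L, 9L, 17L), each = 4),
                   x = rep(c(15, 50, 90), each = 4) + runif(12, -1, 1),
                   y = rep(c(80, 30, 60), each = 4) + runif(12, -1, 1),
                   polarity = rep(c("appearing", "vanishing", "appearing"),
                                  each = 4),
                   size = 5L, balance = 0)
  cl <- meanshift_cluster(ev)
  perm <- sample(nrow(ev))
  cl_p <- meanshift_cluster(ev[perm, ])
  expect_equal(nrow(cl$clusters), nrow(cl_p$clusters))
  expect_equal(sort(cl$clusters$x), sort(cl_p$clusters$x), tolerance = 1e-3)

  # re-clustering the modes reproduces the modes
  modes <- cl$clusters
  ev_m <- data.frame(id = seq_len(nrow(modes)), pair = modes$pair,
                     x = modes$x, y = modes$y, polarity = modes$polarity,
                     size = 5L, balance = 0)
  cl2 <- meanshift_cluster(ev_m)
  expect_equal(nrow(cl2$clusters), nrow(modes))
  expect_equal(sort(round(cl2$clusters$x, 2)), sort(round(modes$x, 2)),
               tolerance = 0.05)
  # never more clusters than events
  expect_lte(nrow(cl$clusters), nrow(ev))
})

test_that("static appearing/vanishing spots yield no discarded clusters", {
  cfg <- sim_config(n_frames = 30, height = 96, width = 96,
                    n_event_spots = 6, spot_intensity = 150, n_movers = 0,
                    min_separation = 15)
  sim <- generate_sequence(cfg, seed = 8)
  norm <- normalize_pipeline(sim$sequence)
  det <- detect(norm, patch_config(control = "fwer"), seed = 1)
  ev <- extract_events(det, norm)
  cl <- meanshift_cluster(ev)
  expect_equal(sum(cl$clusters$discarded), 0L)
  expect_gt(nrow(cl$clusters), 0L)
})

test_that("event rates split by polarity and sum to the total", {
  cl <- list(clusters = data.frame(
    cluster = 1:4, x = 0, y = 0, pair = 1,
    n = 1L, polarity = c("appearing", "appearing", "vanishing", "appearing"),
    discarded = c(FALSE, FALSE, FALSE, TRUE)))
  class(cl) <- "event_clusters"
  r <- event_rate(cl, 100)
  expect_equal(unname(r["appearing"]), 0.02)
  expect_equal(unname(r["vanishing"]), 0.01)
  expect_equal(unname(r["total"]), unname(r["appearing"] + r["vanishing"]))

  empty <- meanshift_cluster(extract_events_empty <- data.frame(
    id = integer(0), pair = integer(0), x = numeric(0), y = numeric(0),
    polarity = character(0), size = integer(0), balance = numeric(0)))
  expect_equal(unname(event_rate(empty, 50)["total"]), 0)
})
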