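test_that("the at-least-two-distances rule decides dimer membership", {
  # far apart on every marker: not a dimer
  far <- make_pair_frame(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0),
                         c(8, 8, 0), c(7, 8, 0), c(9, 8, 0))
  expect_false(is_dimer(peptide_markers(far), "p1", "p2", 1))

  # exactly two distances below cutoff (COM-COM = 0.9, C-C = 0.8)
  close2 <- make_pair_frame(
    com_a = c(0, 0, 0), n_a = c(-2, 0, 0), c_a = c(2, 0, 0),
    com_b = c(0.9, 0, 0), n_b = c(0.9, 3, 0), c_b = c(2.8, 0, 0))
  m <- peptide_markers(close2)
  d_nn <- sqrt(sum((c(-2, 0, 0) - c(0.9, 3, 0))^2))
  expect_gt(d_nn, 1) # confirm the constructed case
  expect_true(is_dimer(m, "p1", "p2", 1))
  # a tighter cutoff rejects it
  expect_false(is_dimer(m, "p1", "p2", 1, cutoff = 0.5))
  expect_error(is_dimer(m, "p1", "p2", 99), "frame")
})

test_that("orientation classification brackets the 90-degree threshold", {
  axis_frame <- function(angle_deg) {
    # exact axis for the 90-degree tie; trig otherwise
    a <- if (angle_deg == 90) c(0, 1, 0) else
      c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
    make_pair_frame(
      com_a = c(0, 0, 0), n_a = c(-0.5, 0, 0), c_a = c(0.5, 0, 0),
      com_b = c(0, 0.5, 0), n_b = c(0, 0.5, 0) - 0.5 * a,
      c_b = c(0, 0.5, 0) + 0.5 * a)
  }
  expect_equal(classify_orientation(peptide_markers(axis_frame(0)),
                                    "p1", "p2", 1), "parallel")
  expect_equal(classify_orientation(peptide_markers(axis_frame(180)),
                                    "p1", "p2", 1), "antiparallel")
  expect_equal(classify_orientation(peptide_markers(axis_frame(89)),
                                    "p1", "p2", 1), "parallel")
  expect_equal(classify_orientation(peptide_markers(axis_frame(91)),
                                    "p1", "p2", 1), "antiparallel")
  # exact 90 degrees ties toward antiparallel
  expect_equal(classify_orientation(peptide_markers(axis_frame(90)),
                                    "p1", "p2", 1), "antiparallel")

  degenerate <- make_pair_frame(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),
                                c(0.5, 0, 0), c(0, 0.5, 0), c(1, 0.5, 0))
  expect_error(classify_orientation(peptide_markers(degenerate),
                                    "p1", "p2", 1), "zero-length")
})

test_that("vectorised classification matches a brute-force oracle", {
  set.seed(1234)
  n_frames <- 30
  ids <- paste0("p", 1:4)
  rows <- list()
  pos <- matrix(runif(12, 0, 4), nrow = 4)
  for (f in seq_len(n_frames)) {
    pos <- pos + matrix(rnorm(12, 0, 0.4), nrow = 4)
    for (i in 1:4) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      com <- pos[i, ]
      for (mk in c("COM", "N", "C")) {
        p <- switch(mk, COM = com, N = com - 0.8 * ax, C = com + 0.8 * ax)
        rows[[length(rows) + 1]] <- marker_row(f, ids[i],
                                               c("A", "A", "B", "B")[i],
                                               mk, p)
      }
    }
  }
  markers <- peptide_markers(dplyr::bind_rows(rows))

  # brute force: recompute the five distances from raw coordinates
  brute_is_dimer <- function(f, a, b) {
    get <- function(id, mk) {
      r <- markers[markers$frame == f & markers$peptide_id == id &
                   markers$marker == mk, ]
      c(r$x, r$y, r$z)
    }
    d <- c(
      sqrt(sum((get(a, "COM") - get(b, "COM"))^2)),
      sqrt(sum((get(a, "N") - get(b, "N"))^2)),
      sqrt(sum((get(a, "C") - get(b, "C"))^2)),
      sqrt(sum((get(a, "N") - get(b, "C"))^2)),
      sqrt(sum((get(a, "C") - get(b, "N"))^2))
    )
    sum(d < 1) >= 2
  }
  n_checked <- 0
  for (f in seq_len(n_frames)) {
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(is_dimer(markers, ids[i], ids[j], f),
                   brute_is_dimer(f, ids[i], ids[j]))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, n_frames * 6)

  # every recorded dimer satisfies the criterion
  stats <- dimer_statistics(markers)
  if (nrow(stats$records) > 0) {
    ok <- mapply(function(f, a, b) brute_is_dimer(f, a, b),
                 stats$records$frame, stats$records$id_a, stats$records$id_b)
    expect_true(all(ok))
  }
})

test_that("statistics are invariant under rigid motion and input order", {
  traj <- simulate_peptide_markers(n_frames = 60, occupancy = 0.4,
                                   orientation = "antiparallel", seed = 77)
  base <- dimer_statistics(traj)

  # random rotation + translation applied to every frame
  set.seed(9)
  qr_rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  shift <- c(3, -2, 5)
  moved <- traj
  xyz <- as.matrix(traj[, c("x", "y", "z")]) %*% qr_rot
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  expect_equal(dimer_statistics(moved)$summary, base$summary,
               tolerance = 1e-12)

  # shuffling the rows changes nothing
  shuffled <- traj[sample(nrow(traj)), ]
  expect_equal(dimer_statistics(shuffled)$summary, base$summary)
})

test_that("greedy pairing counts each peptide at most once", {
  # three mutually close peptides: only the closest pair forms a dimer
  rows <- dplyr::bind_rows(
    marker_row(1, "a", "A", "COM", c(0, 0, 0)),
    marker_row(1, "a", "A", "N", c(-0.5, 0, 0)),
    marker_row(1, "a", "A", "C", c(0.5, 0, 0)),
    marker_row(1, "b", "A", "COM", c(0.4, 0, 0)),
    marker_row(1, "b", "A", "N", c(-0.1, 0, 0)),
    marker_row(1, "b", "A", "C", c(0.9, 0, 0)),
    marker_row(1, "c", "B", "COM", c(0, 0.6, 0)),
    marker_row(1, "c", "B", "N", c(-0.5, 0.6, 0)),
    marker_row(1, "c", "B", "C", c(0.5, 0.6, 0))
  )
  stats <- dimer_statistics(peptide_markers(rows))
  expect_equal(nrow(stats$records), 1)
  expect_setequal(c(stats$records$id_a, stats$records$id_b), c("a", "b"))
  expect_equal(sum(stats$summary$mean_count), 1)
  expect_equal(stats$summary$mean_count[
    stats$summary$class == "parallel" & stats$summary$kind == "homo"], 1)
})

test_that("counts average over frames and recover planted occupancy", {
  # dimer present in one of two frames -> 0.5
  two <- dplyr::bind_rows(
    make_pair_frame(c(0, 0, 0), c(-0.5, 0, 0), c(0.5, 0, 0),
                    c(0.4, 0.3, 0), c(-0.1, 0.3, 0), c(0.9, 0.3, 0),
                    frame = 1),
    make_pair_frame(c(0, 0, 0), c(-0.5, 0, 0), c(0.5, 0, 0),
                    c(6, 6, 0), c(5.5, 6, 0), c(6.5, 6, 0), frame = 2)
  )
  stats <- dimer_statistics(peptide_markers(two))
  expect_equal(sum(stats$summary$mean_count), 0.5)
  expect_equal(stats$summary$mean_count[
    stats$summary$class == "parallel" & stats$summary$kind == "hetero"], 0.5)

  traj <- simulate_peptide_markers(n_frames = 400, occupancy = 0.3,
                                   seed = 31)
  got <- dimer_statistics(traj)
  expect_lt(abs(sum(got$summary$mean_count) - 0.3), 0.05)
  # planted parallel heterodimers land in the right bin
  expect_equal(sum(got$summary$mean_count),
               got$summary$mean_count[got$summary$class == "parallel" &
                                      got$summary$kind == "hetero"])
})

test_that("periodic boxes use the minimum-image convention", {
  near_edge <- make_pair_frame(
    com_a = c(0.3, 5, 5), n_a = c(0.3, 4.5, 5), c_a = c(0.3, 5.5, 5),
    com_b = c(9.8, 5, 5), n_b = c(9.8, 4.5, 5), c_b = c(9.8, 5.5, 5))
  no_box <- peptide_markers(near_edge)
  expect_false(is_dimer(no_box, "p1", "p2", 1))
  with_box <- near_edge
  with_box$box_x <- 10; with_box$box_y <- 10; with_box$box_z <- 10
  m <- peptide_markers(with_box)
  expect_true(is_dimer(m, "p1", "p2", 1)) # wrapped distance is 0.5 nm
  expect_equal(classify_orientation(m, "p1", "p2", 1), "parallel")
})

test_that("marker tables are validated and round-trip through CSV", {
  bad <- make_pair_frame(c(0, 0, 0), c(-1, 0, 0), c(1, 0, 0),
                         c(8, 8, 0), c(7, 8, 0), c(9, 8, 0))[-1, ]
  expect_error(peptide_markers(bad), "3 markers")
  traj <- simulate_peptide_markers(n_frames = 5, seed = 3, box = 12)
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(traj), f, row.names = FALSE)
  back <- read_peptide_markers(f)
  expect_equal(dimer_statistics(back)$summary, dimer_statistics(traj)$summary)
})
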