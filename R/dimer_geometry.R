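## Coarse-grained peptide dimer criterion and orientation classification.
##
## Each peptide per frame is reduced to three markers: center of mass (COM),
## N-terminus (N) and C-terminus (C), in nm.  Two peptides are a dimer in a
## frame when at least two of the marker-pair distances {COM-COM, N-N, C-C,
## N-C, C-N} are below a 1 nm cutoff; a dimer is parallel when the N->C axes
## of the two helices point the same way (positive dot product).

.default_distance_set <- c("COM-COM", "N-N", "C-C", "N-C", "C-N")

#' Validate a peptide marker table
#'
#' @param df Data frame with columns `frame`, `peptide_id`, `species`,
#'   `marker` (one of `"COM"`, `"N"`, `"C"`), `x`, `y`, `z` (nm), and
#'   optionally `box_x`, `box_y`, `box_z` for periodic systems.
#' @return The validated tibble (class `peptide_markers`).
#' @export
peptide_markers <- function(df) {
  need <- c("frame", "peptide_id", "species", "marker", "x", "y", "z")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("marker table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$marker %in% c("COM", "N", "C"))) {
    stop("marker must be one of COM, N, C", call. = FALSE)
  }
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  cnt <- table(df$peptide_id, df$frame)
  if (any(cnt != 3)) {
    stop("every peptide needs exactly 3 markers in every frame",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("peptide_markers", class(out))
  out
}

#' Read a marker table from CSV
#'
#' @param path CSV file with the columns described in [peptide_markers()].
#' @return A `peptide_markers` tibble.
#' @export
read_peptide_markers <- function(path) {
  peptide_markers(utils::read.csv(path, stringsAsFactors = FALSE))
}

## 3x3 coordinate matrix (rows COM, N, C) of one peptide in one frame.
.marker_matrix <- function(markers, id, frame) {
  m <- markers[markers$peptide_id == id & markers$frame == frame, ,
               drop = FALSE]
  if (nrow(m) == 0) stop("no markers for peptide ", id, " in frame ", frame,
                         call. = FALSE)
  rows <- match(c("COM", "N", "C"), m$marker)
  out <- as.matrix(m[rows, c("x", "y", "z")])
  rownames(out) <- c("COM", "N", "C")
  out
}

.box_of <- function(markers, frame) {
  if (!all(c("box_x", "box_y", "box_z") %in% names(markers))) return(NULL)
  b <- markers[markers$frame == frame, c("box_x", "box_y", "box_z")][1, ]
  as.numeric(b)
}

## Distance with minimum-image convention when a box is given.
.mi_dist <- function(a, b, box = NULL) {
  d <- a - b
  if (!is.null(box)) d <- d - box * round(d / box)
  sqrt(sum(d^2))
}

## Named marker-pair distances between two peptides.
.pair_distances <- function(ma, mb, box = NULL,
                            distances = .default_distance_set) {
  pick <- function(tag) {
    ends <- strsplit(tag, "-")[[1]]
    .mi_dist(ma[ends[1], ], mb[ends[2], ], box)
  }
  stats::setNames(vapply(distances, pick, 0), distances)
}

#' Dimer criterion for one peptide pair in one frame
#'
#' TRUE when at least two of the configured marker-pair distances are below
#' the cutoff.  Distances use the minimum-image convention when the marker
#' table carries box columns.
#'
#' @param markers A [peptide_markers()] tibble.
#' @param id_a,id_b Peptide identifiers.
#' @param frame Frame number.
#' @param cutoff Distance cutoff, nm (default 1.0).
#' @param distances Which marker pairs enter the at-least-two rule.
#' @return Logical flag.
#' @export
is_dimer <- function(markers, id_a, id_b, frame, cutoff = 1.0,
                     distances = .default_distance_set) {
  ma <- .marker_matrix(markers, id_a, frame)
  mb <- .marker_matrix(markers, id_b, frame)
  d <- .pair_distances(ma, mb, .box_of(markers, frame), distances)
  sum(d < cutoff) >= 2
}

#' Mutual orientation of a peptide pair
#'
#' Parallel when the N->C axis vectors have a positive dot product (angle
#' below 90 degrees); the tie at exactly 90 degrees classifies as
#' antiparallel.
#'
#' @inheritParams is_dimer
#' @return `"parallel"` or `"antiparallel"`.
#' @export
classify_orientation <- function(markers, id_a, id_b, frame) {
  ma <- .marker_matrix(markers, id_a, frame)
  mb <- .marker_matrix(markers, id_b, frame)
  va <- ma["C", ] - ma["N", ]
  vb <- mb["C", ] - mb["N", ]
  if (sum(va^2) == 0 || sum(vb^2) == 0) {
    stop("zero-length N->C axis", call. = FALSE)
  }
  if (sum(va * vb) > 0) "parallel" else "antiparallel"
}

#' Time-averaged dimer statistics
#'
#' Per frame, candidate pairs satisfying the dimer criterion are paired
#' greedily by ascending COM distance with each peptide in at most one
#' dimer (avoiding double counting in transient triplets); each dimer is
#' classified parallel/antiparallel and homo/hetero.  Counts are averaged
#' over all frames.
#'
#' @param markers A [peptide_markers()] tibble.
#' @param cutoff Distance cutoff, nm.
#' @param distances Marker pairs entering the criterion.
#' @return List of class `dimer_stats`: `records` (tibble `frame`, `id_a`,
#'   `id_b`, `class`, `kind`), `summary` (tibble `class`, `kind`,
#'   `mean_count` over frames), `n_frames`.
#' @export
dimer_statistics <- function(markers, cutoff = 1.0,
                             distances = .default_distance_set) {
  markers <- peptide_markers(markers)
  frames <- sort(unique(markers$frame))
  ids <- sort(unique(markers$peptide_id))
  species <- stats::setNames(
    markers$species[match(ids, markers$peptide_id)], ids)
  recs <- list()
  for (f in frames) {
    box <- .box_of(markers, f)
    mats <- lapply(ids, .marker_matrix, markers = markers, frame = f)
    names(mats) <- ids
    cand <- list()
    if (length(ids) >= 2) {
      for (i in seq_along(ids)[-length(ids)]) {
        for (j in seq((i + 1), length(ids))) {
          d <- .pair_distances(mats[[i]], mats[[j]], box, distances)
          if (sum(d < cutoff) >= 2) {
            com <- .mi_dist(mats[[i]]["COM", ], mats[[j]]["COM", ], box)
            cand[[length(cand) + 1]] <- list(i = i, j = j, com = com)
          }
        }
      }
    }
    if (length(cand) > 0) {
      cand <- cand[order(vapply(cand, `[[`, 0, "com"))]
      used <- logical(length(ids))
      for (cd in cand) {
        if (used[cd$i] || used[cd$j]) next
        used[cd$i] <- used[cd$j] <- TRUE
        ia <- ids[cd$i]; ib <- ids[cd$j]
        recs[[length(recs) + 1]] <- tibble::tibble(
          frame = f, id_a = ia, id_b = ib,
          class = classify_orientation(markers, ia, ib, f),
          kind = if (species[[as.character(ia)]] ==
                     species[[as.character(ib)]]) "homo" else "hetero"
        )
      }
    }
  }
  records <- if (length(recs)) dplyr::bind_rows(recs) else {
    tibble::tibble(frame = integer(), id_a = character(),
                   id_b = character(), class = character(),
                   kind = character())
  }
  summary <- tidyr::complete(
    dplyr::count(records, .data$class, .data$kind),
    class = c("parallel", "antiparallel"), kind = c("homo", "hetero"),
    fill = list(n = 0L)
  )
  summary$mean_count <- summary$n / length(frames)
  summary$n <- NULL
  structure(list(records = records, summary = summary,
                 n_frames = length(frames)),
            class = "dimer_stats")
}

#' @export
print.dimer_stats <- function(x, ...) {
  cat(sprintf("<dimer_stats> %d frames, %d dimer records\n",
              x$n_frames, nrow(x$records)))
  print(x$summary)
  invisible(x)
}

#' Tidy dimer statistics
#'
#' @param x A `dimer_stats` object.
#' @param ... Unused.
#' @return The per-(class, kind) summary tibble.
#' @export
tidy.dimer_stats <- function(x, ...) x$summary

#' Simulate a two-peptide marker trajectory with planted dimer occupancy
#'
#' In each frame the pair is in a dimer with probability `occupancy`
#' (markers placed within the cutoff, in the requested orientation) and far
#' apart otherwise.  Useful as a ground-truth fixture for the classifier.
#'
#' @param n_frames Number of frames.
#' @param occupancy Probability that a frame contains the dimer.
#' @param orientation `"parallel"` or `"antiparallel"` for planted dimers.
#' @param species Length-2 character vector of species labels.
#' @param box Optional cubic box edge, nm (adds box columns).
#' @param seed Integer seed.
#' @return A [peptide_markers()] tibble.
#' @export
simulate_peptide_markers <- function(n_frames = 100, occupancy = 0.3,
                                     orientation = "parallel",
                                     species = c("A", "B"), box = NULL,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  helix <- 1.5 # N->C marker half-length, nm
  for (f in seq_len(n_frames)) {
    dimer <- stats::runif(1) < occupancy
    base <- stats::runif(3, 2, 8)
    jitter <- function() stats::rnorm(3, 0, 0.05)
    com_a <- base
    if (dimer) {
      com_b <- base + c(0, 0.6, 0)
    } else {
      com_b <- base + c(4, 4, 0)
    }
    dir_a <- c(1, 0, 0)
    dir_b <- if (orientation == "parallel" || !dimer) c(1, 0, 0) else
      c(-1, 0, 0)
    add <- function(id, sp, com, dir) {
      for (mk in c("COM", "N", "C")) {
        pos <- switch(mk, COM = com, N = com - helix * dir,
                      C = com + helix * dir) + jitter()
        rows[[length(rows) + 1]] <<- tibble::tibble(
          frame = f, peptide_id = id, species = sp, marker = mk,
          x = pos[1], y = pos[2], z = pos[3])
      }
    }
    add("p1", species[1], com_a, dir_a)
    add("p2", species[2], com_b, dir_b)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(box)) {
    out$box_x <- box; out$box_y <- box; out$box_z <- box
  }
  peptide_markers(out)
}
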