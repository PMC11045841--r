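# Multi-frame XYZ input/output with `time=` / `state=` comment tokens and a
# delimited hop-event sidecar.  Two on-disk layouts are supported:
#   xyz_dir    one multi-frame XYZ file per trajectory in a directory,
#              plus an optional `hops.tsv` sidecar;
#   xyz_concat a single multi-frame XYZ file whose comment lines carry a
#              `traj=` token delimiting trajectories.

.parse_comment_tokens <- function(line) {
  toks <- regmatches(line, gregexpr("[A-Za-z_]+=[^[:space:]]+", line))[[1]]
  if (length(toks) == 0) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  setNames(lapply(kv, function(p) p[2]), vapply(kv, function(p) p[1], ""))
}

# parse one multi-frame XYZ chunk (character vector of lines) into a list of
# frames; `file` is used for error messages only
.parse_xyz_lines <- function(lines, file = "<xyz>") {
  frames <- list()
  i <- 1L
  frame_no <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    frame_no <- frame_no + 1L
    if (is.na(nat) || nat <= 0) {
      abort(sprintf("malformed XYZ atom-count line in '%s' (frame %d)",
                    file, frame_no))
    }
    if (i + 1L + nat > length(lines)) {
      abort(sprintf("truncated XYZ frame %d in '%s'", frame_no, file))
    }
    comment <- lines[i + 1L]
    body <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (any(vapply(parts, length, integer(1)) < 4)) {
      abort(sprintf("malformed atom line in '%s' (frame %d)", file, frame_no))
    }
    labels <- vapply(parts, `[[`, "", 1)
    xyz <- matrix(suppressWarnings(
      as.numeric(unlist(lapply(parts, function(p) p[2:4])))),
      ncol = 3, byrow = TRUE)
    if (anyNA(xyz)) {
      abort(sprintf("non-numeric coordinate in '%s' (frame %d)", file, frame_no))
    }
    frames[[frame_no]] <- list(labels = labels, xyz = xyz,
                               tokens = .parse_comment_tokens(comment))
    i <- i + 2L + nat
  }
  frames
}

.frames_to_trajectory <- function(frames, id, file, default_dt = 1) {
  nat <- vapply(frames, function(f) nrow(f$xyz), integer(1))
  if (length(unique(nat)) > 1) {
    abort(sprintf("inconsistent atom counts across frames of '%s'", file))
  }
  coords <- array(NA_real_, dim = c(length(frames), nat[[1]], 3))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]$xyz
  times <- vapply(seq_along(frames), function(k) {
    t <- frames[[k]]$tokens$time
    if (is.null(t)) (k - 1) * default_dt else as.numeric(t)
  }, numeric(1))
  states <- vapply(seq_along(frames), function(k) {
    s <- frames[[k]]$tokens$state
    if (is.null(s)) 1L else as.integer(s)
  }, integer(1))
  trajectory(id, coords, times, states,
             meta = list(atom_labels = frames[[1]]$labels, source = file))
}

#' Read a trajectory ensemble from disk
#'
#' @param root Directory (`layout = "xyz_dir"`) or single file
#'   (`layout = "xyz_concat"`).
#' @param layout On-disk layout dialect, `"xyz_dir"` or `"xyz_concat"`.
#' @param dihedral_map Optional dihedral map attached to the ensemble
#'   (see [ensemble()]).
#' @param dt Nominal frame spacing in fs used when frames carry no `time=`
#'   token (default 1).
#' @return An [ensemble()].  XYZ comment lines are scanned for `time=` and
#'   `state=` tokens; frames without a `state=` token default to S1.  A
#'   `hops.tsv` sidecar (columns `traj_id`, `frame`, `from`, `to`) found in
#'   `root` (or next to the concatenated file) is attached to the matching
#'   trajectories.
#' @export
read_ensemble <- function(root, layout = c("xyz_dir", "xyz_concat"),
                          dihedral_map = NULL, dt = 1) {
  layout <- match.arg(layout)
  if (!file.exists(root)) abort(sprintf("input path '%s' does not exist", root))
  if (layout == "xyz_dir") {
    files <- sort(list.files(root, pattern = "\\.xyz$", full.names = TRUE))
    if (length(files) == 0) abort(sprintf("no .xyz files under '%s'", root))
    trajs <- lapply(files, function(f) {
      frames <- .parse_xyz_lines(readLines(f), file = f)
      .frames_to_trajectory(frames, id = sub("\\.xyz$", "", basename(f)),
                            file = f, default_dt = dt)
    })
    sidecar <- file.path(root, "hops.tsv")
  } else {
    frames <- .parse_xyz_lines(readLines(root), file = root)
    ids <- vapply(seq_along(frames), function(k) {
      frames[[k]]$tokens$traj %||% "traj"
    }, character(1))
    trajs <- lapply(unique(ids), function(id) {
      .frames_to_trajectory(frames[ids == id], id = id, file = root,
                            default_dt = dt)
    })
    sidecar <- file.path(dirname(root), "hops.tsv")
  }
  if (file.exists(sidecar)) {
    hops <- utils::read.delim(sidecar, sep = "\t", stringsAsFactors = FALSE)
    trajs <- lapply(trajs, function(tr) {
      h <- hops[hops$traj_id == tr$id, , drop = FALSE]
      if (nrow(h) > 0) {
        tr$hops <- tibble(frame = as.integer(h$frame),
                          from = as.integer(h$from), to = as.integer(h$to))
      }
      tr
    })
  }
  dts <- unlist(lapply(trajs, function(tr) diff(tr$times)))
  ensemble(trajs, dihedral_map = dihedral_map,
           dt = if (length(dts)) stats::median(dts) else dt)
}

#' Write a trajectory ensemble to disk
#'
#' Writes one multi-frame XYZ file per trajectory (comment lines carry
#' `time=` and `state=` tokens, coordinates formatted `%.6f`) plus a
#' `hops.tsv` sidecar with one row per hop event.
#'
#' @param e An [ensemble()].
#' @param root Output directory, created if needed.
#' @return Invisibly, the character vector of paths written.
#' @export
write_ensemble <- function(e, root) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  if (length(e$trajectories) == 0) {
    warn("writing an empty ensemble: no XYZ files produced")
  }
  paths <- character(0)
  hop_rows <- list()
  for (tr in e$trajectories) {
    f <- file.path(root, paste0(tr$id, ".xyz"))
    labels <- tr$meta$atom_labels %||% e$atom_labels %||%
      rep("C", n_atoms(tr))
    con <- file(f, "w")
    for (k in seq_len(n_frames(tr))) {
      cat(sprintf("%d\n", n_atoms(tr)), file = con)
      cat(sprintf("traj=%s time=%.6f state=%d\n", tr$id, tr$times[k],
                  tr$states[k]), file = con)
      cat(sprintf("%s %.6f %.6f %.6f\n", labels,
                  tr$coords[k, , 1], tr$coords[k, , 2], tr$coords[k, , 3]),
          file = con, sep = "")
    }
    close(con)
    paths <- c(paths, f)
    if (!is.null(tr$hops) && nrow(tr$hops) > 0) {
      hop_rows[[tr$id]] <- tibble(traj_id = tr$id, frame = tr$hops$frame,
                                  from = tr$hops$from, to = tr$hops$to)
    }
  }
  sidecar <- file.path(root, "hops.tsv")
  hops <- if (length(hop_rows)) dplyr::bind_rows(hop_rows) else
    tibble(traj_id = character(), frame = integer(),
           from = integer(), to = integer())
  utils::write.table(hops, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sidecar))
}
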