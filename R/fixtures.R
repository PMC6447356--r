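## On-disk fixture sets: one directory per participant with 8-bit PNG
## images, 0/255 PNG truth masks, a PTS landmark file, a JSON spec echo,
## and a top-level CSV manifest. Everything round-trips losslessly
## through the package readers.

#' Write participant bundles to a fixture directory
#'
#' @param bundles a single [generate_participant()] bundle or a list of
#'   them.
#' @param dir output directory (created if needed).
#' @return The manifest `data.frame` (one row per file), invisibly; also
#'   written as `manifest.csv` in `dir`.
#' @export
write_fixture_set <- function(bundles, dir) {
  if (inherits(bundles, "participant_bundle")) bundles <- list(bundles)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create fixture directory: %s", dir))
  rows <- list()
  add <- function(pid, kind, formulation, path) {
    rows[[length(rows) + 1L]] <<- data.frame(
      participant_id = pid, kind = kind, formulation = formulation,
      path = path)
  }
  for (b in bundles) {
    pid <- b$spec$participant_id
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    rel <- function(f) file.path(pid, f)
    write_uv_png(b$baseline, file.path(pdir, "baseline.png"))
    add(pid, "baseline", NA_character_, rel("baseline.png"))
    for (f in names(b$applied)) {
      write_uv_png(b$applied[[f]], file.path(pdir, sprintf("applied_%s.png", f)))
      add(pid, "applied", f, rel(sprintf("applied_%s.png", f)))
      write_mask_png(b$truth_covered[[f]],
                     file.path(pdir, sprintf("truth_%s.png", f)))
      add(pid, "truth", f, rel(sprintf("truth_%s.png", f)))
    }
    write_pts(b$landmarks, file.path(pdir, "landmarks.pts"))
    add(pid, "landmarks", NA_character_, rel("landmarks.pts"))
    spec_out <- b$spec
    class(spec_out) <- NULL
    spec_out$seed <- b$seed
    jsonlite::write_json(spec_out, file.path(pdir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
    add(pid, "spec", NA_character_, rel("spec.json"))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a fixture directory back into participant inputs
#'
#' @param dir directory written by [write_fixture_set()].
#' @return Named list (by participant id) of lists with `baseline`,
#'   `applied`, `truth_covered`, `landmarks`, `spec`.
#' @export
read_fixture_set <- function(dir) {
  man_path <- file.path(dir, "manifest.csv")
  if (!file.exists(man_path)) stop(sprintf("no manifest.csv in %s", dir))
  manifest <- read.csv(man_path, stringsAsFactors = FALSE)
  out <- list()
  for (pid in unique(manifest$participant_id)) {
    rows <- manifest[manifest$participant_id == pid, ]
    entry <- list(applied = list(), truth_covered = list())
    spec_row <- rows[rows$kind == "spec", ]
    if (nrow(spec_row)) {
      entry$spec <- jsonlite::read_json(file.path(dir, spec_row$path[1L]),
                                        simplifyVector = TRUE)
    }
    base_row <- rows[rows$kind == "baseline", ]
    entry$baseline <- read_uv_png(file.path(dir, base_row$path[1L]),
                                  meta = list(participant = pid,
                                              condition = "baseline"))
    dims <- dim(working_channel(entry$baseline))
    for (i in which(rows$kind == "applied")) {
      f <- rows$formulation[i]
      entry$applied[[f]] <- read_uv_png(file.path(dir, rows$path[i]),
                                        meta = list(participant = pid,
                                                    condition = f))
    }
    for (i in which(rows$kind == "truth")) {
      entry$truth_covered[[rows$formulation[i]]] <-
        read_mask_png(file.path(dir, rows$path[i]))
    }
    lm_row <- rows[rows$kind == "landmarks", ]
    entry$landmarks <- load_landmarks(file.path(dir, lm_row$path[1L]),
                                      image_dims = dims)
    out[[pid]] <- entry
  }
  out
}
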