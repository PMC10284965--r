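#' Read a pipeline configuration file
#'
#' Flat YAML with optional per-module sections `palate`, `plate` and
#' `nicp`; every key defaults to the package default (the clinical design
#' values: 0.1 mm contact offset, 2 mm thickness, 2.5 mm safety
#' distance). Unknown keys raise an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return list with elements `palate` (argument list for
#'   [palate_params()]), `plate` (a [plate_params()]) and `nicp`
#'   (a [nicp_config()]).
#' @export
read_plate_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  take <- function(section, fn) {
    args <- cfg[[section]]
    if (is.null(args)) args <- list()
    known <- names(formals(fn))
    bad <- setdiff(names(args), known)
    if (length(bad))
      stop(sprintf("unknown %s config keys: %s", section,
                   paste(bad, collapse = ", ")))
    args
  }
  list(palate = take("palate", palate_params),
       plate = do.call(plate_params, take("plate", plate_params)),
       nicp = do.call(nicp_config, take("nicp", nicp_config)))
}

#' Serialize landmarks to and from JSON
#'
#' The on-disk format is a named list `{name: {position: [x,y,z],
#' prob: p}}`.
#'
#' @param landmarks a [landmark_set()].
#' @param path output / input JSON file.
#' @return `write_landmarks_json` returns the path;
#'   `read_landmarks_json` a [landmark_set()].
#' @export
write_landmarks_json <- function(landmarks, path) {
  obj <- lapply(seq_len(nrow(landmarks$positions)), function(j) {
    out <- list(position = as.numeric(landmarks$positions[j, ]))
    if (!is.null(landmarks$probabilities))
      out$prob <- landmarks$probabilities[j]
    out
  })
  names(obj) <- rownames(landmarks$positions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- do.call(rbind, lapply(obj, function(l) as.numeric(l$position)))
  rownames(pos) <- names(obj)
  probs <- vapply(obj, function(l)
    if (is.null(l$prob)) NA_real_ else as.numeric(l$prob), 0)
  if (anyNA(probs)) probs <- NULL
  landmark_set(pos, probabilities = probs)
}

#' Serialize ground truth (landmarks + labels) to JSON
#'
#' @param scan a `palate_scan`.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(scan, path) {
  obj <- list(
    landmarks = lapply(seq_len(nrow(scan$landmarks$positions)), function(j)
      as.numeric(scan$landmarks$positions[j, ])),
    labels = as.character(scan$labels))
  names(obj$landmarks) <- rownames(scan$landmarks$positions)
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
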