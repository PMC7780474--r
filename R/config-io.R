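#' Read specimen configurations from the canonical CSV table
#'
#' The canonical interchange format is a UTF-8 comma-separated table with
#' header `specimen,label,class,region,curve_id,ordinal,side,x,y,z` (missing
#' fields empty). Rows are grouped by specimen; every specimen must carry
#' exactly the same ordered point set as the first.
#'
#' @param path file path.
#' @return Named list of [LandmarkConfig-class], one per specimen.
#' @seealso [writeConfigurations()], [readPts()]
#' @export
readConfigurations <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("specimen", "label", "class", "region", "curve_id", "ordinal", "side", "x", "y", "z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("configuration table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(tab$side) || all(is.na(tab$side))) tab$side <- "none"
  tab$side[is.na(tab$side)] <- "none"
  specs <- unique(tab$specimen)
  out <- list()
  ref_labels <- NULL
  for (s in specs) {
    rows <- tab[tab$specimen == s, , drop = FALSE]
    if (is.null(ref_labels)) {
      ref_labels <- rows$label
    } else if (!identical(rows$label, ref_labels)) {
      extra <- setdiff(rows$label, ref_labels)
      miss <- setdiff(ref_labels, rows$label)
      stop(sprintf(
        "specimen '%s' point set differs from '%s': missing {%s}, extra {%s}",
        s, specs[1L], paste(miss, collapse = ","), paste(extra, collapse = ",")
      ))
    }
    cfg <- LandmarkConfig(s,
      rows[, c("label", "class", "region", "curve_id", "ordinal", "side")],
      as.matrix(rows[, c("x", "y", "z")])
    )
    validObject(cfg)
    out[[s]] <- cfg
  }
  out
}

#' Write configurations to the canonical CSV table
#'
#' @param configs a [LandmarkConfig-class] or list of them.
#' @param path output file path.
#' @return `invisible(path)`.
#' @export
writeConfigurations <- function(configs, path) {
  if (is(configs, "LandmarkConfig")) configs <- list(configs)
  rows <- do.call(rbind, lapply(configs, function(cfg) {
    cbind(
      data.frame(specimen = cfg@specimenId, stringsAsFactors = FALSE),
      cfg@points,
      as.data.frame(cfg@coords, row.names = FALSE)
    )
  }))
  rownames(rows) <- NULL
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a Landmark-Editor-style .pts file (read-only importer)
#'
#' Plain text, one point per line: `label x y z` (comment lines starting with
#' a quote or hash are skipped). All points are imported as class `landmark`;
#' reclassify with the canonical table for curve and surface points.
#'
#' @param path file path.
#' @param specimenId identifier for the resulting configuration; default is
#'   the file base name.
#' @return A [LandmarkConfig-class].
#' @export
readPts <- function(path, specimenId = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^[\"'#]", lines)]
  tok <- strsplit(lines, "\\s+")
  tok <- tok[vapply(tok, length, 1L) >= 4L]
  if (!length(tok)) stop("no point records found in ", path)
  labels <- vapply(tok, `[`, "", 1L)
  xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3L)))
  LandmarkConfig(
    specimenId,
    data.frame(
      label = labels, class = "landmark", region = "all",
      curve_id = NA_character_, ordinal = NA_integer_, side = "none",
      stringsAsFactors = FALSE
    ),
    xyz
  )
}

#' Drop points from a configuration
#'
#' Removes points by label or by predicate, preserving the order of the
#' survivors. Used to remove non-comparable landmarks and curves (negligible
#' regions, multi-template regions, negligible-hole fences) before a joint
#' alignment.
#'
#' @param config a [LandmarkConfig-class].
#' @param what character vector of labels, or a predicate taking the point
#'   metadata data.frame and returning a logical vector of points to drop.
#' @return The reduced [LandmarkConfig-class].
#' @export
dropPoints <- function(config, what) {
  pts <- config@points
  if (is.function(what)) {
    drop <- what(pts)
    if (!is.logical(drop) || length(drop) != nrow(pts)) {
      stop("predicate must return one logical per point")
    }
  } else {
    unknown <- setdiff(what, pts$label)
    if (length(unknown)) stop("unknown labels: ", paste(unknown, collapse = ", "))
    drop <- pts$label %in% what
  }
  if (all(drop)) stop("dropping all points would leave an empty configuration")
  keep <- which(!drop)
  newpts <- pts[keep, , drop = FALSE]
  # renumber curve ordinals so survivors stay consecutive from 0
  for (cid in unique(newpts$curve_id[newpts$class == "curve"])) {
    sel <- which(newpts$class == "curve" & newpts$curve_id %in% cid)
    newpts$ordinal[sel] <- order(newpts$ordinal[sel]) - 1L
  }
  cfg <- LandmarkConfig(config@specimenId, newpts, config@coords[keep, , drop = FALSE])
  validObject(cfg)
  cfg
}
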