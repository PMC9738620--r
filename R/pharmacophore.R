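# Typed-feature pharmacophore models derived from anchor residues of a
# bound peptide: hydrophobic features are side-chain heavy-atom centroids,
# positive-ionizable features are charged-group centroids.

#' Derive a pharmacophore model from anchor residues
#'
#' For each anchor, the feature centroid is the unweighted mean of the
#' contributing heavy atoms: for `"hydrophobic"` anchors all side-chain
#' heavy atoms (everything except N, CA, C, O, OXT -- CB included, since it
#' carries the side-chain direction); for `"positive_ionic"` anchors the
#' charged-group atoms (Arg: NE+CZ+NH1+NH2, Lys: NZ, His: ND1+NE2). The
#' full symmetric pairwise centroid distance matrix is returned. Features
#' are ordered canonically by (chain, residue number), so the anchor order
#' does not affect the result.
#'
#' @param model A `structure_model`.
#' @param anchors data.frame with columns `chain`, `res_seq`, `kind`
#'   (`"hydrophobic"` or `"positive_ionic"`), or a character vector of
#'   `"chain:res_seq:kind"` strings.
#' @return Object of class `pharmacophore_model`: `features` data.frame
#'   (`kind`, `chain`, `res_seq`, `res_name`, `n_atoms`, `x`, `y`, `z`)
#'   and `dist` (symmetric matrix, Angstrom).
#' @export
derive_features <- function(model, anchors) {
  if (is.character(anchors)) {
    parts <- strsplit(anchors, ":", fixed = TRUE)
    bad <- vapply(parts, length, 1L) != 3
    if (any(bad)) stop("anchor strings must be chain:res_seq:kind")
    anchors <- data.frame(
      chain = vapply(parts, `[`, "", 1),
      res_seq = as.integer(vapply(parts, `[`, "", 2)),
      kind = vapply(parts, `[`, "", 3), stringsAsFactors = FALSE)
  }
  anchors$kind[anchors$kind == "positive"] <- "positive_ionic"
  unknown <- setdiff(anchors$kind, c("hydrophobic", "positive_ionic"))
  if (length(unknown) > 0) {
    stop("unknown feature kind(s): ", paste(unknown, collapse = ", "))
  }
  anchors <- anchors[order(anchors$chain, anchors$res_seq), , drop = FALSE]
  a <- model$atoms
  feats <- list()
  for (i in seq_len(nrow(anchors))) {
    rows <- a[a$chain == anchors$chain[i] & a$res_seq == anchors$res_seq[i], ,
              drop = FALSE]
    if (nrow(rows) == 0) {
      stop("anchor residue ", anchors$chain[i], ":", anchors$res_seq[i],
           " not found")
    }
    res_name <- rows$res_name[1]
    sel <- if (anchors$kind[i] == "hydrophobic") {
      rows[!rows$atom_name %in% c("N", "CA", "C", "O", "OXT") &
             !rows$element %in% c("H", "D"), , drop = FALSE]
    } else {
      grp <- positive_group_atoms[[res_name]]
      if (is.null(grp)) {
        stop("residue ", res_name, " has no positive-ionizable group")
      }
      hit <- rows[rows$atom_name %in% grp, , drop = FALSE]
      if (nrow(hit) == 0) {
        # coarse models (e.g. toy pseudo-side-chains) lack the charged-group
        # atoms; fall back to whatever side-chain heavy atoms exist
        hit <- rows[!rows$atom_name %in% c("N", "CA", "C", "O", "OXT") &
                      !rows$element %in% c("H", "D"), , drop = FALSE]
      }
      hit
    }
    if (nrow(sel) == 0) {
      stop("anchor ", anchors$chain[i], ":", anchors$res_seq[i], " (",
           res_name, ") has no contributing atoms for kind ", anchors$kind[i])
    }
    feats[[i]] <- data.frame(
      kind = anchors$kind[i], chain = anchors$chain[i],
      res_seq = anchors$res_seq[i], res_name = res_name,
      n_atoms = nrow(sel), x = mean(sel$x), y = mean(sel$y),
      z = mean(sel$z), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  xyz <- as.matrix(features[, c("x", "y", "z")])
  dm <- as.matrix(dist(xyz))
  dimnames(dm) <- list(res_label(features$res_name, features$res_seq),
                       res_label(features$res_name, features$res_seq))
  structure(list(features = features, dist = dm),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat("pharmacophore_model:", nrow(x$features), "features (",
      sum(x$features$kind == "hydrophobic"), "hydrophobic,",
      sum(x$features$kind == "positive_ionic"), "positive )\n")
  print(round(x$dist, 1))
  invisible(x)
}

#' Export a pharmacophore model
#'
#' Writes feature kinds, centroids (3 decimals) and the full distance
#' matrix as TSV (two sections) or JSON.
#'
#' @param model A `pharmacophore_model`.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_model <- function(model, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "pharmacophore_model"))
  if (nrow(model$features) < 1) stop("model has no features")
  f <- model$features
  f$x <- round(f$x, 3); f$y <- round(f$y, 3); f$z <- round(f$z, 3)
  if (format == "json") {
    jsonlite::write_json(list(features = f,
                              dist = round(model$dist, 3)),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# features", con)
    write.table(f, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines("# distance_matrix", con)
    write.table(round(model$dist, 3), con, sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}

#' Import a pharmacophore model written by [export_model()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`.
#' @return A `pharmacophore_model`.
#' @export
import_model <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    features <- as.data.frame(obj$features, stringsAsFactors = FALSE)
    dm <- as.matrix(obj$dist)
  } else {
    lines <- readLines(path)
    sep <- which(lines == "# distance_matrix")
    features <- read.delim(text = lines[2:(sep - 1)], stringsAsFactors = FALSE)
    dm <- as.matrix(read.delim(text = lines[(sep + 1):length(lines)],
                               row.names = 1, check.names = FALSE))
  }
  labs <- res_label(features$res_name, features$res_seq)
  dimnames(dm) <- list(labs, labs)
  structure(list(features = features, dist = dm),
            class = "pharmacophore_model")
}
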