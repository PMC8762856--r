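## Classifier database: forest maintenance and versioned persistence.

#' Supported on-disk format version for `.ctdb` archives
#' @export
CTDB_FORMAT_VERSION <- "1.0"

#' Add a classifier to a database
#'
#' The database is a forest: names are unique (case-sensitive) and every
#' parent must already be present. Cell-type names may not contain `"/"`,
#' which is reserved for ambiguous assignments.
#'
#' @param db a [ClassifierDatabase-class].
#' @param classifier a [CellClassifier-class].
#' @return The extended database.
#' @examples
#' db <- classifierDatabase()
#' @export
addClassifier <- function(db, classifier) {
  stopifnot(is(db, "ClassifierDatabase"), is(classifier, "CellClassifier"))
  nm <- cellType(classifier)
  if (grepl("/", nm, fixed = TRUE))
    ctStop("validity_error",
           "cell-type name '%s' contains '/', reserved for ambiguous assignments", nm)
  if (nm %in% names(db@entries))
    ctStop("name_collision_error",
           "a classifier named '%s' already exists", nm)
  p <- parentType(classifier)
  if (!is.na(p) && !p %in% names(db@entries))
    ctStop("unresolved_parent_error",
           "parent '%s' of '%s' is not in the database", p, nm)
  db@entries[[nm]] <- classifier
  db
}

#' Remove a classifier, re-rooting its children
#'
#' Children of the removed node are attached to the removed node's own
#' parent (or become roots). Use repeated leaf removal to delete a whole
#' subtree.
#'
#' @param db a [ClassifierDatabase-class].
#' @param cell_type name of the classifier to remove.
#' @return The reduced database.
#' @export
removeClassifier <- function(db, cell_type) {
  stopifnot(is(db, "ClassifierDatabase"))
  if (!cell_type %in% names(db@entries))
    ctStop("not_found_error", "no classifier named '%s' in the database",
           cell_type)
  grand <- db@entries[[cell_type]]@parent
  db@entries[[cell_type]] <- NULL
  for (nm in names(db@entries)) {
    if (identical(db@entries[[nm]]@parent, cell_type))
      db@entries[[nm]]@parent <- grand
  }
  db
}

#' Check database invariants
#'
#' Returns violation descriptions instead of raising, so broken databases
#' can be inspected. Checks: entry names match classifier cell types,
#' every parent resolves, and the parent relation is acyclic.
#'
#' @param db a [ClassifierDatabase-class].
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validateDatabase <- function(db) {
  stopifnot(is(db, "ClassifierDatabase"))
  msgs <- character(0)
  nms <- names(db@entries)
  if (is.null(nms) && length(db@entries)) nms <- rep("", length(db@entries))
  for (i in seq_along(db@entries)) {
    ct <- db@entries[[i]]@cell_type
    if (!identical(nms[i], ct))
      msgs <- c(msgs, sprintf(
        "name mismatch: entry key '%s' vs classifier cell_type '%s'",
        nms[i], ct))
  }
  if (anyDuplicated(nms))
    msgs <- c(msgs, sprintf("duplicate cell-type names: %s",
                            paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  parent <- vapply(db@entries, function(e) e@parent, character(1))
  for (i in seq_along(parent)) {
    if (!is.na(parent[i]) && !parent[i] %in% nms)
      msgs <- c(msgs, sprintf("dangling parent: '%s' refers to unknown '%s'",
                              nms[i], parent[i]))
  }
  ## Cycle detection by walking parent chains; each cycle reported once.
  seen_cycles <- list()
  state <- setNames(integer(length(nms)), nms)   # 0 new, 1 on path, 2 done
  for (start in nms) {
    if (!length(start) || is.na(start) || state[start] != 0L) next
    path <- character(0)
    node <- start
    while (!is.na(node) && node %in% nms && state[node] == 0L) {
      state[node] <- 1L
      path <- c(path, node)
      node <- parent[node]
    }
    if (!is.na(node) && node %in% nms && state[node] == 1L) {
      cyc <- sort(path[seq(match(node, path), length(path))])
      key <- paste(cyc, collapse = "|")
      if (!key %in% names(seen_cycles)) {
        seen_cycles[[key]] <- cyc
        msgs <- c(msgs, sprintf("cycle in parent relation: %s",
                                paste(cyc, collapse = " -> ")))
      }
    }
    state[path] <- 2L
  }
  msgs
}

## Topological order: parents before children. Assumes a valid forest.
topoOrder <- function(db) {
  nms <- names(db@entries)
  parent <- vapply(db@entries, function(e) e@parent, character(1))
  depth <- setNames(integer(length(nms)), nms)
  for (nm in nms) {
    d <- 0L
    p <- parent[nm]
    while (!is.na(p) && p %in% nms) {
      d <- d + 1L
      p <- parent[p]
      if (d > length(nms)) break
    }
    depth[nm] <- d
  }
  nms[order(depth, seq_along(nms))]
}

## Children of each node, preserving database order.
childrenMap <- function(db) {
  nms <- names(db@entries)
  parent <- vapply(db@entries, function(e) e@parent, character(1))
  lapply(setNames(nms, nms), function(nm) nms[!is.na(parent) & parent == nm])
}

## All descendants of `cell_type` in the database (excluding itself).
descendantsOf <- function(db, cell_type) {
  kids <- childrenMap(db)
  out <- character(0)
  queue <- kids[[cell_type]]
  while (length(queue)) {
    out <- c(out, queue[1L])
    queue <- c(queue[-1L], kids[[queue[1L]]])
  }
  out
}

## Lossless double <-> base64 (little-endian IEEE-754).
encodeDoubles <- function(x)
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
decodeDoubles <- function(s, n)
  readBin(jsonlite::base64_dec(s), "numeric", n = n, size = 8L,
          endian = "little")

#' Save a classifier database to a `.ctdb` archive
#'
#' One JSON file: a human-readable manifest (names, parents, thresholds,
#' features, format version) with every real-valued array additionally
#' base64-encoded as IEEE-754 doubles so the round trip is bit-exact.
#'
#' @param db a valid [ClassifierDatabase-class].
#' @param path output file path (conventionally `*.ctdb`).
#' @return `path`, invisibly.
#' @export
saveDatabase <- function(db, path) {
  stopifnot(is(db, "ClassifierDatabase"))
  viol <- validateDatabase(db)
  if (length(viol))
    ctStop("validation_error", "refusing to save an invalid database: %s",
           paste(viol, collapse = "; "))
  entries <- lapply(db@entries, function(e) {
    m <- e@model
    list(cell_type = e@cell_type,
         parent = if (is.na(e@parent)) NULL else e@parent,
         threshold = e@threshold,
         threshold_bin = encodeDoubles(e@threshold),
         features = as.list(m@feature_names),
         n_features = length(m@feature_names),
         weights_bin = encodeDoubles(m@weights),
         intercept_bin = encodeDoubles(m@intercept),
         platt_a_bin = encodeDoubles(m@platt_a),
         platt_b_bin = encodeDoubles(m@platt_b),
         feature_means_bin = encodeDoubles(m@feature_means),
         feature_sds_bin = encodeDoubles(m@feature_sds))
  })
  doc <- list(format = "ctdb", format_version = db@format_version,
              classifiers = unname(entries))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    ctStop("io_error", "cannot write archive to '%s': %s", path,
           conditionMessage(ok))
  invisible(path)
}

requireField <- function(x, field, where) {
  if (is.null(x[[field]]))
    ctStop("parse_error", "malformed archive: missing field '%s' in %s",
           field, where)
  x[[field]]
}

#' Load a classifier database from a `.ctdb` archive
#'
#' @param path path to an archive written by [saveDatabase()].
#' @return A [ClassifierDatabase-class], field-identical to the saved one.
#' @export
loadDatabase <- function(path) {
  if (!file.exists(path))
    ctStop("io_error", "archive '%s' does not exist", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    ctStop("parse_error", "malformed archive '%s': %s",
                           path, conditionMessage(e)))
  ver <- requireField(doc, "format_version", "manifest")
  if (!identical(ver, CTDB_FORMAT_VERSION))
    ctStop("version_error",
           "unsupported format_version '%s' (supported: %s)",
           ver, CTDB_FORMAT_VERSION)
  db <- classifierDatabase(format_version = ver)
  entries <- requireField(doc, "classifiers", "manifest")
  for (rec in entries) {
    ct <- requireField(rec, "cell_type", "classifier record")
    nf <- requireField(rec, "n_features", ct)
    feats <- vapply(requireField(rec, "features", ct), as.character,
                    character(1))
    model <- linearBinaryModel(
      feature_names = feats,
      weights = decodeDoubles(requireField(rec, "weights_bin", ct), nf),
      intercept = decodeDoubles(requireField(rec, "intercept_bin", ct), 1L),
      platt_a = decodeDoubles(requireField(rec, "platt_a_bin", ct), 1L),
      platt_b = decodeDoubles(requireField(rec, "platt_b_bin", ct), 1L),
      feature_means = decodeDoubles(requireField(rec, "feature_means_bin", ct), nf),
      feature_sds = decodeDoubles(requireField(rec, "feature_sds_bin", ct), nf))
    clf <- cellClassifier(
      cell_type = ct, model = model,
      threshold = decodeDoubles(requireField(rec, "threshold_bin", ct), 1L),
      parent = if (is.null(rec$parent)) NA_character_ else rec$parent)
    db@entries[[ct]] <- clf
  }
  viol <- validateDatabase(db)
  if (length(viol))
    ctStop("validation_error", "archive contains an invalid database: %s",
           paste(viol, collapse = "; "))
  db
}
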