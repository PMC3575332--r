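# Genotype matrices for pseudo-testcross (CP) progenies.
#
# Internal call alphabet: "h" = heterozygous-like, "a" = homozygous-like,
# NA = missing.  Missing is a first-class state and is never conflated with
# a homozygous call.

.CALL_HET <- "h"
.CALL_HOM <- "a"

# Surface-code dialects accepted on input.  JoinMap CP testcross codes
# (lm/ll for <lmxll> markers, np/nn for <nnxnp>) and the simplified a/h
# alphabet both normalize onto the internal three-state representation.
.default_code_map <- c(
  lm = "h", np = "h", h = "h",
  ll = "a", nn = "a", a = "a"
)
.missing_codes <- c("-", "--", "", "NA", "na", "u")

#' Construct a genotype matrix
#'
#' A `geno_matrix` is a rectangular marker x individual table of testcross
#' genotype calls, with a linkage-group assignment and a dense 0-based
#' within-group order for every marker.  Rows are markers, columns are
#' individuals; cells are `"h"` (heterozygous-like), `"a"`
#' (homozygous-like) or `NA` (missing).
#'
#' @param calls character matrix of calls with unique row names (marker
#'   ids) and column names (individual ids); values in `c("h", "a", NA)`,
#'   or any surface code accepted by `code_map`.
#' @param lg vector of linkage-group labels, one per marker.
#' @param order integer vector of 0-based ranks within each linkage group;
#'   if `NULL`, markers get ranks in order of appearance within each group.
#' @param code_map named character vector mapping surface codes onto
#'   `"h"`/`"a"`; defaults cover JoinMap CP (`lm`, `ll`, `np`, `nn`) and the
#'   simplified `a`/`h` alphabet.  `-`, `--` and empty cells become `NA`.
#' @return an object of class `geno_matrix` with elements `calls`, `lg`
#'   and `order`.
#' @examples
#' m <- matrix(c("h", "a", "h", NA, "a", "a"), nrow = 3,
#'             dimnames = list(paste0("M", 1:3), c("i1", "i2")))
#' gm <- geno_matrix(m, lg = c(1, 1, 1))
#' missing_stats(gm)$overall
#' @export
geno_matrix <- function(calls, lg, order = NULL, code_map = NULL) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have marker row names and individual column names")
  calls[] <- normalize_calls(calls, code_map)
  lg <- as.character(lg)
  if (length(lg) != nrow(calls))
    stop("`lg` must have one entry per marker")
  if (is.null(order)) {
    order <- integer(nrow(calls))
    for (g in unique(lg)) {
      idx <- which(lg == g)
      order[idx] <- seq_along(idx) - 1L
    }
  }
  order <- as.integer(order)
  gm <- structure(list(calls = calls, lg = lg, order = order),
                  class = "geno_matrix")
  validate_geno_matrix(gm)
  gm
}

# Map surface codes onto the internal alphabet; unknown codes raise.
normalize_calls <- function(x, code_map = NULL) {
  map <- if (is.null(code_map)) .default_code_map else code_map
  out <- as.character(x)
  out[out %in% .missing_codes | is.na(out)] <- NA_character_
  hit <- !is.na(out)
  known <- out[hit] %in% names(map)
  if (!all(known)) {
    bad <- unique(out[hit][!known])
    stop("invalid genotype code(s): ", paste(bad, collapse = ", "))
  }
  out[hit] <- unname(map[out[hit]])
  out
}

validate_geno_matrix <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- gm$calls
  if (anyDuplicated(rownames(calls)))
    stop("duplicate marker ids")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate individual ids")
  ok <- is.na(calls) | calls %in% c(.CALL_HET, .CALL_HOM)
  if (!all(ok)) stop("invalid call values after normalization")
  for (g in unique(gm$lg)) {
    o <- sort(gm$order[gm$lg == g])
    if (!identical(o, seq_along(o) - 1L))
      stop("order is not a dense 0-based permutation within linkage group ", g)
  }
  invisible(gm)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d markers x %d individuals, %d linkage group(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$lg))))
  ms <- missing_stats(x)
  cat(sprintf("  missing: %.1f%% of %d data points\n",
              100 * ms$overall, ms$n_total))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

n_markers     <- function(gm) nrow(gm$calls)
n_individuals <- function(gm) ncol(gm$calls)
marker_ids    <- function(gm) rownames(gm$calls)

# Subset markers, keeping relative order and re-densifying ranks.
subset_markers <- function(gm, idx) {
  calls <- gm$calls[idx, , drop = FALSE]
  lg <- gm$lg[idx]
  ord <- gm$order[idx]
  new_order <- integer(length(ord))
  for (g in unique(lg)) {
    j <- which(lg == g)
    new_order[j][order(ord[j])] <- seq_along(j) - 1L
  }
  structure(list(calls = calls, lg = lg, order = new_order),
            class = "geno_matrix")
}

# Row indices of a group's markers sorted by within-group order.
group_marker_index <- function(gm, group) {
  idx <- which(gm$lg == as.character(group))
  if (length(idx) == 0L) stop("unknown linkage group: ", group)
  idx[order(gm$order[idx])]
}

#' Classify the segregation type of a marker from its parental calls
#'
#' In a CP progeny a marker segregates in one of three configurations:
#' heterozygous only in parent 1 (ABxAA, JoinMap `<lmxll>`), only in
#' parent 2 (AAxAB, `<nnxnp>`), or in both (ABxAB, `<hkxhk>`).  Markers
#' homozygous in both parents do not segregate and are rejected.
#'
#' @param parent1_call,parent2_call zygosity of each parent: `"het"` or
#'   `"hom"` (the internal codes `"h"`/`"a"` are also accepted).
#'   Vectorized.
#' @return character vector over `"ABxAA"`, `"AAxAB"`, `"ABxAB"`.
#' @examples
#' classify_segregation("het", "hom")  # "ABxAA"
#' @export
classify_segregation <- function(parent1_call, parent2_call) {
  norm <- function(x) {
    x <- as.character(x)
    x[x %in% c("het", .CALL_HET)] <- "het"
    x[x %in% c("hom", .CALL_HOM)] <- "hom"
    if (!all(x %in% c("het", "hom")))
      stop("parental calls must be 'het' or 'hom'")
    x
  }
  p1 <- norm(parent1_call)
  p2 <- norm(parent2_call)
  if (any(p1 == "hom" & p2 == "hom"))
    stop("monomorphic marker: homozygous in both parents does not segregate")
  ifelse(p1 == "het" & p2 == "hom", "ABxAA",
         ifelse(p1 == "hom" & p2 == "het", "AAxAB", "ABxAB"))
}

#' Split a genotype matrix into the two uni-parental testcross sets
#'
#' Only markers heterozygous in exactly one parent segregate 1:1 and can be
#' mapped on that parent's testcross map; markers heterozygous in both
#' parents are discarded.
#'
#' @param gm a [geno_matrix()].
#' @param classes per-marker segregation classes (`"ABxAA"`, `"AAxAB"`,
#'   `"ABxAB"`), aligned with the markers of `gm`.
#' @return list with `parent1` (ABxAA markers), `parent2` (AAxAB markers),
#'   both `geno_matrix` objects with re-densified order, and `n_discarded`.
#' @export
filter_uniparental <- function(gm, classes) {
  classes <- as.character(classes)
  if (length(classes) != n_markers(gm))
    stop("`classes` must align with the markers of `gm`")
  if (!all(classes %in% c("ABxAA", "AAxAB", "ABxAB")))
    stop("unknown segregation class")
  list(parent1 = subset_markers(gm, classes == "ABxAA"),
       parent2 = subset_markers(gm, classes == "AAxAB"),
       n_discarded = sum(classes == "ABxAB"))
}

# ---- phase-aware encoding ----------------------------------------------

phase_signs <- function(phases) {
  phases <- as.character(phases)
  if (!all(phases %in% c("1-", "0-")))
    stop("phases must be '1-' or '0-'")
  ifelse(phases == "1-", 1L, -1L)
}

#' Assign marker phases greedily along the given order
#'
#' The first marker of each linkage group is anchored at phase `"1-"`;
#' each subsequent marker takes the phase under which its calls agree with
#' the preceding marker's encoding for the majority of individuals
#' non-missing at both (linked neighbors rarely recombine, so agreement is
#' the expected state).  Ties and no-overlap cases keep the previous phase.
#'
#' @param gm a [geno_matrix()].
#' @return named character vector of phases (`"1-"`/`"0-"`) per marker.
#' @export
assign_phases <- function(gm) {
  phases <- setNames(rep("1-", n_markers(gm)), marker_ids(gm))
  calls <- gm$calls
  for (g in unique(gm$lg)) {
    idx <- group_marker_index(gm, g)
    if (length(idx) < 2L) next
    for (j in 2:length(idx)) {
      prev <- calls[idx[j - 1L], ]
      cur <- calls[idx[j], ]
      both <- !is.na(prev) & !is.na(cur)
      agree <- sum(prev[both] == cur[both])
      disagree <- sum(both) - agree
      prev_phase <- phases[rownames(calls)[idx[j - 1L]]]
      phases[rownames(calls)[idx[j]]] <-
        if (disagree > agree) setdiff(c("1-", "0-"), prev_phase) else prev_phase
    }
  }
  phases
}

#' Encode one individual's calls on one linkage group
#'
#' Calls are mapped onto `{1, 0, -1}` according to genotype and phase:
#' heterozygous in phase `"1-"` or homozygous in phase `"0-"` encode as
#' `1`; homozygous in phase `"1-"` or heterozygous in phase `"0-"` encode
#' as `-1`; missing encodes as `0`.
#'
#' @param gm a [geno_matrix()].
#' @param phases named phase vector as from [assign_phases()].
#' @param individual individual id.
#' @param group linkage-group label.
#' @return list with `values` (integer vector over `{1, 0, -1}`),
#'   `positions` (0-based within-group order of each entry) and `markers`.
#' @export
encode <- function(gm, phases, individual, group) {
  if (!individual %in% colnames(gm$calls))
    stop("unknown individual: ", individual)
  X <- encode_group(gm, phases, group)
  list(values = X[, individual],
       positions = seq_len(nrow(X)) - 1L,
       markers = rownames(X))
}

# Encode all individuals of one group at once: ordered markers x
# individuals integer matrix over {1, 0, -1}.
encode_group <- function(gm, phases, group) {
  idx <- group_marker_index(gm, group)
  ids <- marker_ids(gm)[idx]
  if (!all(ids %in% names(phases)))
    stop("phase missing for marker(s): ",
         paste(setdiff(ids, names(phases)), collapse = ", "))
  p <- phase_signs(phases[ids])
  calls <- gm$calls[idx, , drop = FALSE]
  g <- matrix(0L, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  g[calls == .CALL_HET] <- 1L
  g[calls == .CALL_HOM] <- -1L
  g * p
}

#' Decode an encoded vector back to genotype calls
#'
#' Inverse of [encode()]: `0` decodes to missing, and the `{1, -1}` states
#' decode through the per-marker phase so that `decode(encode(x)) == x`
#' on non-missing calls.
#'
#' @param values integer vector over `{1, 0, -1}`.
#' @param phases phase (`"1-"`/`"0-"`) per entry, recycled if length 1.
#' @return character vector of calls (`"h"`, `"a"`, `NA`).
#' @export
decode <- function(values, phases) {
  values <- as.integer(values)
  if (!all(values %in% c(-1L, 0L, 1L)))
    stop("encoded values must lie in {1, 0, -1}")
  p <- phase_signs(rep_len(as.character(phases), length(values)))
  g <- values * p
  out <- rep(NA_character_, length(values))
  out[g == 1L] <- .CALL_HET
  out[g == -1L] <- .CALL_HOM
  out
}

#' Missing-data summary of a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @return list with `per_individual` and `per_marker` missing fractions,
#'   the `overall` fraction, and `n_total` = markers x individuals.
#' @export
missing_stats <- function(gm) {
  calls <- gm$calls
  if (length(calls) == 0L) stop("empty genotype matrix")
  miss <- is.na(calls)
  list(per_individual = colMeans(miss),
       per_marker = rowMeans(miss),
       overall = mean(miss),
       n_total = length(calls))
}

# ---- file I/O ----------------------------------------------------------

#' Read a genotype matrix from TSV
#'
#' Expected layout: a header row `marker_id  lg  order  <ind_1> ... <ind_n>`
#' followed by one tab-separated row per marker.  Lines starting with `#`
#' are ignored.  Calls may use the JoinMap CP codes (`lm`/`ll`/`np`/`nn`),
#' the simplified `a`/`h` alphabet, or a custom `code_map`; `-` and `--`
#' denote missing.
#'
#' @param path file path.
#' @param code_map optional surface-code map, see [geno_matrix()].
#' @return a [geno_matrix()].
#' @export
read_genotype_tsv <- function(path, code_map = NULL) {
  raw <- readLines(path)
  keep <- which(!grepl("^\\s*#", raw) & nzchar(trimws(raw)))
  if (length(keep) < 2L) stop("no data rows in ", path)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 4L || !identical(header[1:3], c("marker_id", "lg", "order")))
    stop("header must start with: marker_id, lg, order")
  inds <- header[-(1:3)]
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != length(header))) {
    bad <- keep[-1L][widths != length(header)][1L]
    stop("ragged row at line ", bad, ": expected ", length(header),
         " fields, found ", widths[widths != length(header)][1L])
  }
  tab <- do.call(rbind, body)
  ids <- tab[, 1L]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate marker id '", dup, "' at line ",
         keep[-1L][which(ids == dup)[2L]])
  }
  ord <- suppressWarnings(as.integer(tab[, 3L]))
  if (anyNA(ord)) stop("non-integer order at line ", keep[-1L][which(is.na(ord))[1L]])
  calls <- tab[, -(1:3), drop = FALSE]
  dimnames(calls) <- list(ids, inds)
  calls_norm <- tryCatch(normalize_calls(calls, code_map), error = function(e) e)
  if (inherits(calls_norm, "error")) {
    bad <- which(apply(calls, 1L, function(r) {
      inherits(tryCatch(normalize_calls(r, code_map), error = function(e) e), "error")
    }))[1L]
    stop("invalid genotype code at line ", keep[-1L][bad], ": ",
         conditionMessage(calls_norm))
  }
  calls[] <- calls_norm
  geno_matrix(calls, lg = tab[, 2L], order = ord)
}

#' Write a genotype matrix as TSV
#'
#' @param gm a [geno_matrix()].
#' @param path output path.
#' @param dialect `"simple"` writes `h`/`a`/`-`; `"joinmap"` writes
#'   `lm`/`ll` or `np`/`nn` depending on each marker's segregation class,
#'   with `--` for missing.
#' @param classes per-marker segregation classes, required for the
#'   `"joinmap"` dialect.
#' @param comment optional `#` comment line(s) written before the header.
#' @export
write_genotype_tsv <- function(gm, path, dialect = c("simple", "joinmap"),
                               classes = NULL, comment = NULL) {
  dialect <- match.arg(dialect)
  calls <- surface_calls(gm, dialect, classes,
                         missing_code = if (dialect == "simple") "-" else "--")
  header <- paste(c("marker_id", "lg", "order", colnames(calls)),
                  collapse = "\t")
  rows <- paste(rownames(calls), gm$lg, gm$order,
                apply(calls, 1L, paste, collapse = "\t"), sep = "\t")
  lines <- c(if (!is.null(comment)) paste0("# ", comment), header, rows)
  writeLines(lines, path)
  invisible(path)
}

surface_calls <- function(gm, dialect, classes, missing_code) {
  calls <- gm$calls
  out <- calls
  if (dialect == "simple") {
    # internal alphabet already is the simple dialect
  } else {
    if (is.null(classes) || length(classes) != n_markers(gm))
      stop("joinmap dialect needs per-marker segregation `classes`")
    if (!all(classes %in% c("ABxAA", "AAxAB")))
      stop("joinmap testcross writer supports only ABxAA / AAxAB markers")
    het <- ifelse(classes == "ABxAA", "lm", "np")
    hom <- ifelse(classes == "ABxAA", "ll", "nn")
    for (i in seq_len(nrow(calls))) {
      out[i, calls[i, ] == .CALL_HET] <- het[i]
      out[i, calls[i, ] == .CALL_HOM] <- hom[i]
    }
  }
  out[is.na(calls)] <- missing_code
  out
}

#' Write a JoinMap CP .loc file
#'
#' Emits the standard cross-pollination locus file: a `name`/`popt = CP`/
#' `nloc`/`nind` header followed by one row per marker carrying its
#' segregation type (`<lmxll>` or `<nnxnp>`) and the individual codes
#' (`lm`/`ll`/`np`/`nn`/`--`).
#'
#' @param gm a [geno_matrix()].
#' @param classes per-marker segregation classes (`"ABxAA"` or `"AAxAB"`).
#' @param path output path.
#' @param pop_name population name written in the header.
#' @export
write_joinmap_loc <- function(gm, classes, path, pop_name = "population") {
  classes <- as.character(classes)
  if (length(classes) != n_markers(gm))
    stop("`classes` must align with the markers of `gm`")
  calls <- surface_calls(gm, "joinmap", classes, missing_code = "--")
  seg <- ifelse(classes == "ABxAA", "<lmxll>", "<nnxnp>")
  lines <- c(paste("name =", pop_name),
             "popt = CP",
             paste("nloc =", n_markers(gm)),
             paste("nind =", n_individuals(gm)),
             paste(rownames(calls), seg,
                   apply(calls, 1L, paste, collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}
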