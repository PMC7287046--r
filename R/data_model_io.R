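#' Construct a drug x cell-line response matrix
#'
#' Container for single-drug response values over a cell-line panel. Values
#' are either dose-response AUC fractions in \[0, 1\] (low AUC = sensitive)
#' or log2 IC50 concentrations in log2(uM). Missing measurements stay `NA`;
#' nothing is imputed at this level.
#'
#' @param values numeric matrix, drugs in rows, cell lines in columns;
#'   dimnames required and unique.
#' @param value_kind `"auc"` or `"log2_ic50"`.
#' @param tissue_of named character vector mapping every cell line to a
#'   tissue label. Defaults to a single `"unknown"` tissue.
#' @return An object of class `response_matrix` with fields `values`,
#'   `value_kind`, `tissue_of`.
#' @export
response_matrix <- function(values, value_kind = c("auc", "log2_ic50"),
                            tissue_of = NULL) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate drug identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate cell-line identifiers")
  if (value_kind == "auc") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop("AUC values outside [0, 1]")
  }
  if (any(rowSums(!is.na(values)) == 0))
    stop("drug with no non-missing value: ",
         paste(rownames(values)[rowSums(!is.na(values)) == 0], collapse = ", "))
  if (is.null(tissue_of))
    tissue_of <- setNames(rep("unknown", ncol(values)), colnames(values))
  missing_tissue <- setdiff(colnames(values), names(tissue_of))
  if (length(missing_tissue))
    stop("cell lines without tissue label: ",
         paste(missing_tissue, collapse = ", "))
  structure(list(values = values, value_kind = value_kind,
                 tissue_of = tissue_of[colnames(values)]),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("response_matrix:", nrow(x$values), "drugs x", ncol(x$values),
      "cell lines (", x$value_kind, "),",
      sum(is.na(x$values)), "missing\n")
  invisible(x)
}

#' Read a drug x cell-line response table
#'
#' Wide layout: first column holds drug identifiers, remaining columns are
#' cell lines. Long layout: columns `drug`, `cell_line`, `value`, and
#' optionally `tissue` and `batch`. Missing values may be empty fields or
#' `"NA"`. Duplicate (drug, cell line) entries are allowed when consistent
#' (deduplicated with a warning); conflicting duplicates are an error. A
#' `batch` column (e.g. screening site) is accepted but only warned about --
#' no batch correction is attempted.
#'
#' @param path delimited text file with a header.
#' @param layout `"wide"` or `"long"`.
#' @param value_kind `"auc"` or `"log2_ic50"`.
#' @param min_cell_lines drop drugs with fewer non-missing values than this
#'   (with a warning). Default 10.
#' @param sep field separator; default tab.
#' @param tissue_of optional named vector overriding any `tissue` column.
#' @return A [response_matrix].
#' @export
read_response_table <- function(path, layout = c("wide", "long"),
                                value_kind = c("auc", "log2_ic50"),
                                min_cell_lines = 10, sep = "\t",
                                tissue_of = NULL) {
  layout <- match.arg(layout)
  value_kind <- match.arg(value_kind)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (layout == "wide") {
    drugs <- as.character(tab[[1]])
    if (anyDuplicated(drugs)) stop("duplicate drug rows in wide table")
    values <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- drugs
  } else {
    need <- c("drug", "cell_line", "value")
    if (!all(need %in% names(tab)))
      stop("long layout requires columns: ", paste(need, collapse = ", "))
    if ("batch" %in% names(tab) && length(unique(tab$batch)) > 1)
      warning("multiple batches present (",
              paste(unique(tab$batch), collapse = ", "),
              "); no batch correction is applied")
    key <- paste(tab$drug, tab$cell_line, sep = "\r")
    if (anyDuplicated(key)) {
      spl <- split(tab$value, key)
      bad <- names(spl)[vapply(spl, function(v)
        length(unique(v[!is.na(v)])) > 1, logical(1))]
      if (length(bad))
        stop("conflicting duplicate entries for: ",
             paste(gsub("\r", "/", bad), collapse = ", "))
      warning(sum(duplicated(key)), " duplicated consistent entr",
              if (sum(duplicated(key)) == 1) "y" else "ies",
              " deduplicated")
      tab <- tab[!duplicated(key), , drop = FALSE]
    }
    drugs <- sort(unique(tab$drug))
    lines <- sort(unique(tab$cell_line))
    values <- matrix(NA_real_, length(drugs), length(lines),
                     dimnames = list(drugs, lines))
    values[cbind(match(tab$drug, drugs), match(tab$cell_line, lines))] <-
      tab$value
    if (is.null(tissue_of) && "tissue" %in% names(tab)) {
      tt <- tab[!duplicated(tab$cell_line), c("cell_line", "tissue")]
      tissue_of <- setNames(as.character(tt$tissue), tt$cell_line)
    }
  }
  if (value_kind == "auc" && any(values < 0 | values > 1, na.rm = TRUE))
    stop("AUC outside [0, 1] in ", path)
  keep <- rowSums(!is.na(values)) >= min_cell_lines
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " drug(s) with < ", min_cell_lines,
            " non-missing values: ",
            paste(rownames(values)[!keep], collapse = ", "))
    values <- values[keep, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("no drugs left after filtering")
  response_matrix(values, value_kind, tissue_of)
}

#' Drug/cell-line annotation container
#'
#' @param targets_of named list: drug -> character vector of target gene
#'   symbols.
#' @param mutated_in named list: cell line -> character vector of affected
#'   (mutated or amplified) gene symbols.
#' @param pathway_of optional named character vector: drug -> pathway or
#'   ontology group label.
#' @param cross_reactive character vector of drugs with known cross
#'   reactivity over multiple pathways (excluded from within-pathway
#'   analyses); must be a subset of `names(pathway_of)`.
#' @return An object of class `annotation`.
#' @export
annotation <- function(targets_of = list(), mutated_in = list(),
                       pathway_of = NULL, cross_reactive = character()) {
  chk <- function(l, what) {
    bad <- vapply(l, function(v) any(!nzchar(v)), logical(1))
    if (any(bad)) stop("empty gene symbol in ", what)
  }
  chk(targets_of, "targets_of")
  chk(mutated_in, "mutated_in")
  if (length(cross_reactive) &&
      !all(cross_reactive %in% names(pathway_of)))
    stop("cross_reactive drugs must have a pathway label")
  structure(list(targets_of = targets_of, mutated_in = mutated_in,
                 pathway_of = pathway_of, cross_reactive = cross_reactive),
            class = "annotation")
}

#' Read drug-target and cell-line-mutation annotation tables
#'
#' Both files are two-column delimited text: `drug`, `target` and
#' `cell_line`, `gene`. An optional pathway table has columns `drug`,
#' `pathway` and an optional logical `cross_reactive` column.
#'
#' @param target_path,mutation_path,pathway_path file paths (pathway
#'   optional).
#' @param sep field separator.
#' @return An [annotation].
#' @export
read_annotation_tables <- function(target_path, mutation_path,
                                   pathway_path = NULL, sep = "\t") {
  tg <- utils::read.table(target_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  mu <- utils::read.table(mutation_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  targets_of <- lapply(split(tg$target, tg$drug), unique)
  mutated_in <- lapply(split(mu$gene, mu$cell_line), unique)
  pathway_of <- NULL; cross <- character()
  if (!is.null(pathway_path)) {
    pw <- utils::read.table(pathway_path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    pathway_of <- setNames(as.character(pw$pathway), pw$drug)
    if ("cross_reactive" %in% names(pw))
      cross <- pw$drug[as.logical(pw$cross_reactive)]
  }
  annotation(targets_of, mutated_in, pathway_of, cross)
}

#' Curated synergy label table
#'
#' One row per (cell line, unordered drug pair) with a binary synergy label.
#' Pairs are stored canonically (lexicographic order of drug identifiers),
#' which removes duplicate-row ambiguity.
#'
#' @param cell_line,drug_a,drug_b,label equal-length vectors; `label` in
#'   {0, 1}.
#' @param source optional source tag per row.
#' @return A `data.frame` of class `synergy_table` with columns `cell_line`,
#'   `drug_a`, `drug_b`, `label`, `source`.
#' @export
synergy_table <- function(cell_line, drug_a, drug_b, label,
                          source = NA_character_) {
  if (any(drug_a == drug_b)) stop("drug_a == drug_b in synergy table")
  if (!all(label %in% c(0, 1))) stop("label must be 0 or 1")
  swap <- drug_a > drug_b
  tmp <- drug_a[swap]; drug_a[swap] <- drug_b[swap]; drug_b[swap] <- tmp
  out <- data.frame(cell_line = as.character(cell_line),
                    drug_a = as.character(drug_a),
                    drug_b = as.character(drug_b),
                    label = as.integer(label),
                    source = rep_len(as.character(source), length(cell_line)),
                    stringsAsFactors = FALSE)
  key <- with(out, paste(cell_line, drug_a, drug_b))
  if (anyDuplicated(key))
    stop("duplicate (cell line, pair) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(out) <- c("synergy_table", "data.frame")
  out
}

#' Read a curated synergy label table
#'
#' Expects columns `cell_line`, `drug_a`, `drug_b`, `label` and optionally
#' `source`.
#' @param path delimited text file.
#' @param sep field separator.
#' @return A [synergy_table].
#' @export
read_synergy_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  synergy_table(tab$cell_line, tab$drug_a, tab$drug_b, tab$label,
                if ("source" %in% names(tab)) tab$source else NA_character_)
}

#' Checkerboard viability plate
#'
#' A dose-combination viability matrix: each drug is titrated in a twofold
#' ladder (plus an untreated zero dose) and viability is expressed as % of
#' the untreated control, so the all-zero-dose cell must be 100 within
#' `norm_tol`.
#'
#' @param drugs character vector of length >= 2.
#' @param doses list (one numeric vector per drug) of dose ladders including
#'   the leading 0; strictly increasing.
#' @param viability numeric array with `dim == lengths(doses)`; % of
#'   control, non-negative.
#' @param replicate integer replicate index.
#' @param units dose units tag (default `"uM"`).
#' @param norm_tol tolerance on the untreated cell (default 5 percentage
#'   points).
#' @return An object of class `checkerboard_plate`.
#' @export
checkerboard_plate <- function(drugs, doses, viability, replicate = 1L,
                               units = "uM", norm_tol = 5) {
  stopifnot(length(drugs) >= 2, length(doses) == length(drugs))
  if (!all(dim(viability) == lengths(doses)))
    stop("viability dimensions must match dose ladders")
  if (any(viability < 0, na.rm = TRUE)) stop("negative viability")
  for (d in doses) {
    if (d[1] != 0) stop("each dose ladder must start at 0 (untreated)")
    if (length(d) > 1 && any(diff(d) <= 0))
      stop("dose ladders must be strictly increasing")
  }
  untreated <- do.call(`[`, c(list(viability), as.list(rep(1, length(drugs)))))
  if (!is.na(untreated) && abs(untreated - 100) > norm_tol)
    stop("untreated cell is ", untreated, ", expected 100 within ", norm_tol)
  structure(list(drugs = drugs, doses = doses, viability = viability,
                 replicate = as.integer(replicate), units = units),
            class = "checkerboard_plate")
}

#' Read a checkerboard plate from long-format text
#'
#' Columns: `dose_a`, `dose_b` (optionally `dose_c`), `viability` and
#' optionally `replicate`; one row per dose combination.
#'
#' @param path delimited text file.
#' @param drugs drug identifiers (length 2 or 3 matching the dose columns).
#' @param sep field separator.
#' @return A [checkerboard_plate].
#' @export
read_plate_table <- function(path, drugs = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  dose_cols <- intersect(c("dose_a", "dose_b", "dose_c"), names(tab))
  if (length(dose_cols) < 2) stop("need at least dose_a and dose_b columns")
  if (is.null(drugs)) drugs <- paste0("drug_", seq_along(dose_cols))
  doses <- lapply(dose_cols, function(cn) sort(unique(tab[[cn]])))
  viability <- array(NA_real_, dim = lengths(doses))
  idx <- vapply(seq_along(dose_cols), function(i)
    match(tab[[dose_cols[i]]], doses[[i]]), integer(nrow(tab)))
  viability[idx] <- tab$viability
  checkerboard_plate(drugs, doses, viability,
                     replicate = if ("replicate" %in% names(tab))
                       tab$replicate[1] else 1L)
}

#' Write atlas geometry to JSON or SVG
#'
#' JSON carries, per drug, the cell polygon vertex list, centroid, weight
#' and the border weights of its adjacent boundaries; this format
#' round-trips through [read_atlas_geometry()]. SVG draws filled cell
#' polygons with stroke width proportional to border weight.
#'
#' @param layout an `atlas_layout` (see [layout_voronoi_treemap()]).
#' @param path output file.
#' @param format `"json"` or `"svg"`.
#' @return `path`, invisibly.
#' @export
write_atlas_geometry <- function(layout, path, format = c("json", "svg")) {
  format <- match.arg(format)
  stopifnot(inherits(layout, "atlas_layout"))
  if (!length(layout$cells)) stop("empty layout")
  if (format == "json") {
    recs <- lapply(names(layout$cells), function(dr) {
      poly <- layout$cells[[dr]]
      list(drug = dr,
           vertices = unname(apply(poly, 1, as.numeric, simplify = FALSE)),
           centroid = as.numeric(poly_centroid(poly)),
           weight = as.numeric(layout$weights[[dr]]))
    })
    borders <- if (!is.null(layout$borders) && nrow(layout$borders)) {
      lapply(seq_len(nrow(layout$borders)), function(i)
        as.list(layout$borders[i, c("drug_a", "drug_b", "weight")]))
    } else list()
    obj <- list(container = unname(apply(layout$container, 1, as.numeric,
                                         simplify = FALSE)),
                threshold = layout$threshold,
                cells = recs, borders = borders)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    bb <- apply(layout$container, 2, range)
    w <- diff(bb[, 1]); h <- diff(bb[, 2])
    sc <- 500 / max(w, h)
    px <- function(p) paste(sprintf("%.3f,%.3f",
                                    (p[, 1] - bb[1, 1]) * sc,
                                    (bb[2, 2] - p[, 2]) * sc),
                            collapse = " ")
    max_bw <- max(c(layout$borders$weight, 1e-12), na.rm = TRUE)
    cols <- grDevices::hcl(h = seq(15, 375, length.out =
                                     length(layout$cells) + 1)[-1],
                           l = 75, c = 45)
    paths <- vapply(seq_along(layout$cells), function(i) {
      sprintf('<path class="cell" id="%s" d="M %s Z" fill="%s" stroke="black" stroke-width="0.5"/>',
              names(layout$cells)[i],
              gsub(" ", " L ", px(layout$cells[[i]]), fixed = TRUE),
              cols[i])
    }, character(1))
    border_lines <- character()
    if (!is.null(layout$borders) && nrow(layout$borders) &&
        !is.null(layout$borders$x1)) {
      b <- layout$borders
      border_lines <- sprintf(
        '<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="black" stroke-width="%.3f"/>',
        (b$x1 - bb[1, 1]) * sc, (bb[2, 2] - b$y1) * sc,
        (b$x2 - bb[1, 1]) * sc, (bb[2, 2] - b$y2) * sc,
        0.5 + 4 * b$weight / max_bw)
    }
    svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %.1f %.1f">',
                     520L, 520L, w * sc, h * sc),
             paths, border_lines,
             '</svg>')
    writeLines(svg, path)
  }
  invisible(path)
}

#' Read atlas geometry written by [write_atlas_geometry()] (JSON)
#'
#' @param path JSON file.
#' @return An `atlas_layout` with cells, container, weights, borders.
#' @export
read_atlas_geometry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cells <- list(); weights <- numeric()
  for (rec in obj$cells) {
    cells[[rec$drug]] <- do.call(rbind, lapply(rec$vertices, unlist))
    weights[rec$drug] <- rec$weight
  }
  borders <- if (length(obj$borders)) {
    do.call(rbind, lapply(obj$borders, function(b)
      data.frame(drug_a = b$drug_a, drug_b = b$drug_b,
                 weight = as.numeric(b$weight),
                 stringsAsFactors = FALSE)))
  } else data.frame(drug_a = character(), drug_b = character(),
                    weight = numeric())
  structure(list(container = do.call(rbind, lapply(obj$container, unlist)),
                 cells = cells, weights = weights,
                 sites = t(vapply(cells, poly_centroid, numeric(2))),
                 borders = borders, threshold = obj$threshold %||% NA_real_),
            class = "atlas_layout")
}

#' Export a drug cluster tree as Newick
#'
#' Merge heights are encoded as branch lengths (each branch length is the
#' height difference between a node and its parent, so root-to-leaf path
#' length equals the root merge height).
#'
#' @param tree a `drug_tree` (see [cluster_drugs()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "drug_tree"))
  if (length(tree$labels) == 1) {
    writeLines(paste0(tree$labels, ";"), path)
    return(invisible(path))
  }
  phy <- ape::as.phylo(tree$hclust)
  # as.phylo() halves merge heights so leaf-to-leaf paths equal them;
  # rescale so each branch carries the full height difference and the
  # root-to-leaf depth equals the root merge height
  phy$edge.length <- phy$edge.length * 2
  ape::write.tree(phy, file = path)
  invisible(path)
}
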