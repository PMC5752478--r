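#' Construct an omics abundance matrix
#'
#' Container for one omics layer: a numeric feature-by-sample matrix on the
#' log2-intensity scale, tagged with the layer it belongs to. All downstream
#' stages (differential expression, OPLS-DA, correlation integration) consume
#' this type and assume log2 scale, so fold changes are plain differences.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   `NA` marks a missing measurement (only expected in the metabolite layer).
#' @param layer One of `"mirna"`, `"protein"`, `"metabolite"`.
#' @param feature_ids,sample_ids Unique identifier vectors; default to the
#'   dimnames of `values`.
#' @return An object of class `omics_matrix`: a list with elements `layer`,
#'   `values` (matrix with feature/sample dimnames).
#' @export
omics_matrix <- function(values, layer = c("mirna", "protein", "metabolite"),
                         feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(feature_ids) || is.null(sample_ids))
    stop("feature and sample identifiers are required")
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("length of 'feature_ids' does not match the row count")
  if (length(sample_ids) != ncol(values))
    stop("length of 'sample_ids' does not match the column count")
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicated feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(layer = layer, values = values), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples, %d missing\n",
              x$layer, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Read a feature-by-sample abundance matrix
#'
#' Expects a delimited text file whose first column holds feature identifiers
#' and whose header row holds sample identifiers. Blank cells become `NA`.
#' Values are taken as-is (the caller declares the scale); nothing is
#' re-transformed.
#'
#' @param path Path to a CSV (default) or TSV file; files ending in `.tsv` or
#'   `.txt` are read as tab-separated.
#' @param layer Omics layer tag, see [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_feature_matrix <- function(path, layer) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (ncol(raw) < 2) stop("expected a feature-id column plus sample columns")
  feature_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell at feature '%s' (row %d), sample '%s' (column %d): '%s'",
                 feature_ids[bad[1, 1]], bad[1, 1], sample_ids[bad[1, 2]],
                 bad[1, 2], cells[bad[1, , drop = FALSE]]))
  omics_matrix(num, layer = layer, feature_ids = feature_ids,
               sample_ids = sample_ids)
}

#' Write a feature matrix to disk
#'
#' Inverse of [read_feature_matrix()]; values are written with 15 significant
#' digits so a write/read round trip reproduces them to well below 1e-9.
#'
#' @param x An [omics_matrix()].
#' @param path Output path (`.csv` or `.tsv` decides the delimiter).
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.15g", v))
  lines <- c(paste(c("feature_id", colnames(x$values)), collapse = sep),
             vapply(seq_len(nrow(x$values)), function(i)
               paste(c(rownames(x$values)[i], fmt(x$values[i, ])),
                     collapse = sep), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read the sample metadata table
#'
#' Two-column tab-separated file mapping `sample_id` to `group`. Group levels
#' are kept in file order.
#'
#' @param path Path to the TSV file (a header line `sample_id<TAB>group` is
#'   recognised and skipped).
#' @return A `data.frame` with columns `sample_id` and `group` (factor with
#'   levels in order of first appearance).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) != 2) stop("expected exactly two columns (sample_id, group)")
  if (identical(tolower(raw[1, 1]), "sample_id")) raw <- raw[-1, , drop = FALSE]
  dup <- raw[[1]][duplicated(raw[[1]])]
  if (length(dup))
    stop("sample id(s) listed more than once: ",
         paste(unique(dup), collapse = ", "))
  sample_metadata(raw[[1]], raw[[2]])
}

#' Construct sample metadata in code
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param group Parallel vector of group labels.
#' @return A `data.frame` with `sample_id` and `group` columns.
#' @export
sample_metadata <- function(sample_id, group) {
  stopifnot(length(sample_id) == length(group))
  if (anyDuplicated(sample_id))
    stop("sample id(s) listed more than once: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  data.frame(sample_id = as.character(sample_id),
             group = factor(group, levels = unique(as.character(group))),
             stringsAsFactors = FALSE)
}

# samples of `meta` belonging to the given group(s), in metadata order
samples_of <- function(meta, groups) {
  meta$sample_id[meta$group %in% groups]
}

#' Validate a two-group contrast
#'
#' Orientation convention: a positive effect means higher abundance in
#' `group_b` (the comparison group) than in `group_a` (the reference).
#'
#' @param group_a,group_b Reference and comparison group labels.
#' @param meta Sample metadata (see [sample_metadata()]) used to check that
#'   both groups exist and have at least the minimum number of samples.
#' @param min_n Minimum samples per group (default 2, enough for a variance).
#' @return A list with elements `a` and `b`.
#' @export
contrast <- function(group_a, group_b, meta = NULL, min_n = 2L) {
  if (identical(group_a, group_b)) stop("contrast groups must differ")
  if (!is.null(meta)) {
    for (g in c(group_a, group_b)) {
      n <- sum(meta$group == g)
      if (n == 0) stop("group not present in metadata: ", g)
      if (n < min_n)
        stop(sprintf("group '%s' has %d sample(s); need >= %d", g, n, min_n))
    }
  }
  list(a = group_a, b = group_b)
}

#' Load a pathway library (GMT membership plus topology edges)
#'
#' @param gmt_path GMT file: one pathway per line,
#'   `id<TAB>name<TAB>member1<TAB>member2...`.
#' @param edges_path Optional TSV with columns `pathway_id`, `member_a`,
#'   `member_b` describing undirected topology edges; pathways without edge
#'   lines get an empty topology.
#' @return A named list of `pathway_def` objects, each a list with
#'   `pathway_id`, `name`, `members` (character) and `edges` (2-column
#'   character matrix).
#' @export
load_pathway_library <- function(gmt_path, edges_path = NULL) {
  if (!file.exists(gmt_path)) stop("file not found: ", gmt_path)
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(trimws(lines))]
  lib <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT line needs id, name and at least one member: ", f[1])
    members <- unique(f[-(1:2)])
    list(pathway_id = f[1], name = f[2], members = members,
         edges = matrix(character(0), ncol = 2,
                        dimnames = list(NULL, c("a", "b"))))
  })
  names(lib) <- vapply(lib, `[[`, character(1), "pathway_id")
  if (anyDuplicated(names(lib)))
    stop("duplicated pathway id(s) in GMT: ",
         paste(unique(names(lib)[duplicated(names(lib))]), collapse = ", "))
  if (!is.null(edges_path)) {
    if (!file.exists(edges_path)) stop("file not found: ", edges_path)
    ed <- utils::read.table(edges_path, header = FALSE, sep = "\t",
                            colClasses = "character",
                            stringsAsFactors = FALSE)
    if (ncol(ed) != 3)
      stop("edges file needs three columns (pathway_id, member_a, member_b)")
    if (identical(tolower(ed[1, 1]), "pathway_id")) ed <- ed[-1, , drop = FALSE]
    for (i in seq_len(nrow(ed))) {
      pid <- ed[i, 1]; a <- ed[i, 2]; b <- ed[i, 3]
      if (!pid %in% names(lib)) stop("edge for unknown pathway: ", pid)
      if (identical(a, b))
        stop(sprintf("self-loop edge '%s' in pathway %s", a, pid))
      for (node in c(a, b))
        if (!node %in% lib[[pid]]$members)
          stop(sprintf("edge endpoint '%s' is not a member of pathway %s",
                       node, pid))
      lib[[pid]]$edges <- rbind(lib[[pid]]$edges, c(a, b))
    }
  }
  lapply(lib, function(p) { class(p) <- "pathway_def"; p })
}

#' Bundled miniature metabolite pathway library
#'
#' A small, hand-curated stand-in for a KEGG-derived compound pathway library:
#' five pathways (TCA cycle; alanine, aspartate and glutamate metabolism;
#' primary bile acid biosynthesis; purine metabolism; glycolysis) with
#' compound-name identifiers and undirected topology edges sketched from the
#' public pathway maps. Intended for the synthetic analyses and tests, not as
#' a biological reference.
#'
#' @return A pathway library as returned by [load_pathway_library()].
#' @export
triomix_library <- function() {
  load_pathway_library(
    system.file("extdata", "minikegg.gmt", package = "triomix"),
    system.file("extdata", "minikegg_edges.tsv", package = "triomix"))
}

#' Run configuration
#'
#' Bundles the decision thresholds used across the pipeline. Defaults mirror
#' the source study's reported criteria: raw p < 0.05 for differential
#' expression, |log2FC| >= 1 for the miRNA layer, VIP > 8 for metabolite
#' selection (note this value presumes raw-intensity-scale fitting; see the
#' methods vignette and [run_pipeline()]), and |r| >= 0.9 with p <= 0.05 for
#' cross-layer correlation edges.
#'
#' @param p_de Significance threshold for differential expression.
#' @param lfc_min Minimum |log2 fold change| for the miRNA layer (the protein
#'   layer conventionally uses 0; see [run_de()]).
#' @param vip_min VIP threshold for metabolite selection.
#' @param r_min,p_edge_max Correlation-edge filters.
#' @param n_ortho Number of orthogonal OPLS components.
#' @param cv_folds Cross-validation folds for Q2.
#' @param seed Integer RNG seed.
#' @param mt_mode Multiple-testing mode, `"raw"` (mirrors the study) or
#'   `"bh"` (Benjamini-Hochberg, recommended for real use).
#' @return A list of class `run_config`.
#' @export
run_config <- function(p_de = 0.05, lfc_min = 1.0, vip_min = 8.0,
                       r_min = 0.9, p_edge_max = 0.05, n_ortho = 1L,
                       cv_folds = 7L, seed = 1L, mt_mode = c("raw", "bh")) {
  mt_mode <- match.arg(mt_mode)
  stopifnot(p_de > 0, p_de <= 1, p_edge_max > 0, p_edge_max <= 1,
            r_min >= 0, r_min <= 1, vip_min > 0, cv_folds >= 2,
            n_ortho >= 0, lfc_min >= 0)
  structure(list(p_de = p_de, lfc_min = lfc_min, vip_min = vip_min,
                 r_min = r_min, p_edge_max = p_edge_max,
                 n_ortho = as.integer(n_ortho),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 mt_mode = mt_mode), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys keep their [run_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

# fixed-format numeric rendering shared by all writers, so identical inputs
# always produce byte-identical files
fmt6 <- function(x) sprintf("%.6f", x)

#' Write a cross-layer edge list as TSV
#'
#' Columns `feat_a layer_a feat_b layer_b r p n`; `r` and `p` are written with
#' fixed six-decimal formatting so repeated runs are byte-comparable.
#'
#' @param edges Edge table from [correlate_layers()] / [filter_edges()].
#' @param path Output path.
#' @export
write_edge_list <- function(edges, path) {
  header <- paste(c("feat_a", "layer_a", "feat_b", "layer_b", "r", "p", "n"),
                  collapse = "\t")
  body <- if (nrow(edges) == 0) character(0) else
    vapply(seq_len(nrow(edges)), function(i)
      paste(c(edges$feat_a[i], edges$layer_a[i], edges$feat_b[i],
              edges$layer_b[i], fmt6(edges$r[i]), fmt6(edges$p[i]),
              as.integer(edges$n[i])), collapse = "\t"), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write a cross-layer correlation network as GraphML
#'
#' Nodes carry a `layer` attribute; edges carry `r`, `p` and `n`.
#'
#' @inheritParams write_edge_list
#' @export
write_network <- function(edges, path) {
  nodes <- unique(data.frame(
    name = c(edges$feat_a, edges$feat_b),
    layer = c(edges$layer_a, edges$layer_b),
    stringsAsFactors = FALSE))
  nodes <- nodes[order(nodes$layer, nodes$name), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$feat_a, to = edges$feat_b,
                   r = edges$r, p = edges$p, n = edges$n,
                   stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
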