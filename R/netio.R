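#' Construct an interaction network
#'
#' Builds an undirected protein--protein interaction network from an edge
#' table. Node identifiers are case-sensitive opaque strings; no gene-symbol
#' normalisation is attempted. Self-loops are dropped (with a warning) and
#' duplicate undirected edges are collapsed, keeping the first weight seen.
#'
#' @param edges a data.frame with columns `node_a`, `node_b` and optionally
#'   `weight` (positive reals; default 1), or a 2/3-column matrix-like object.
#' @param nodes optional character vector of node identifiers to retain even
#'   if isolated.
#' @param name network label.
#' @return an [igraph::graph] object (undirected, simple, `weight` edge
#'   attribute, `name` graph attribute).
#' @export
interaction_network <- function(edges, nodes = NULL, name = "network") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs at least 2 columns")
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(a))
  w[is.na(w)] <- 1
  if (any(w <= 0)) stop("edge weights must be > 0")

  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  # undirected dedup: (a,b) == (b,a); first occurrence wins
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  keep <- !duplicated(key)
  a <- a[keep]; b <- b[keep]; w <- w[keep]

  verts <- sort(unique(c(a, b, as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
  igraph::graph_attr(g, "name") <- name
  g
}

#' Read a network from an edge-list or SIF file
#'
#' Edge lists are 2- or 3-column (tab or whitespace separated) `node_a
#' node_b [weight]` files; lines starting with `#` are ignored, except that a
#' header comment of the form `# nodes: id1 id2 ...` declares isolated nodes
#' to retain. SIF rows are `nodeA relation nodeB [nodeC ...]`; every
#' (nodeA, nodeX) pair becomes an unweighted edge.
#'
#' @param path file path.
#' @param format `"edgelist"` or `"sif"`.
#' @param name network label (defaults to the file name).
#' @return an undirected [igraph::graph].
#' @export
read_network <- function(path, format = c("edgelist", "sif"),
                         name = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  iso <- character(0)
  hdr <- grepl("^#\\s*nodes:", lines)
  if (any(hdr)) {
    iso <- unlist(strsplit(sub("^#\\s*nodes:\\s*", "", lines[hdr]), "\\s+"))
    iso <- iso[nzchar(iso)]
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))

  ea <- character(0); eb <- character(0); ew <- numeric(0)
  for (i in body_idx) {
    f <- strsplit(trimws(lines[i]), "[\t ]+")[[1L]]
    if (format == "edgelist") {
      if (length(f) < 2L || length(f) > 3L)
        stop(sprintf("malformed edge-list line %d: '%s'", i, lines[i]))
      wt <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3L])) else 1
      if (is.na(wt))
        stop(sprintf("malformed weight on line %d: '%s'", i, lines[i]))
      ea <- c(ea, f[1L]); eb <- c(eb, f[2L]); ew <- c(ew, wt)
    } else {
      if (length(f) == 1L) { iso <- c(iso, f); next }  # lone node row
      if (length(f) < 3L)
        stop(sprintf("malformed SIF line %d: '%s'", i, lines[i]))
      for (tgt in f[-(1:2)]) {
        ea <- c(ea, f[1L]); eb <- c(eb, tgt); ew <- c(ew, 1)
      }
    }
  }
  edges <- data.frame(node_a = ea, node_b = eb, weight = ew,
                      stringsAsFactors = FALSE)
  interaction_network(edges, nodes = iso, name = name)
}

#' Write a network as a tab-separated edge list
#'
#' Columns `node_a`, `node_b`, `weight`, with isolated nodes recorded in a
#' `# nodes:` header comment so that [read_network()] round-trips.
#'
#' @param net an undirected [igraph::graph].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  if (is.null(el$weight)) el$weight <- 1
  iso <- igraph::V(net)$name[igraph::degree(net) == 0]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#node_a\tnode_b\tweight", con)
  if (length(iso)) writeLines(paste("# nodes:", paste(iso, collapse = " ")), con)
  if (nrow(el))
    writeLines(sprintf("%s\t%s\t%s", el$from, el$to,
                       formatC(el$weight, format = "g", digits = 15)), con)
  invisible(path)
}

#' Construct a disease/phenotype target set
#'
#' @param name set label (disease or phenotype).
#' @param genes character vector of node identifiers; duplicates collapsed
#'   with a warning, order of first occurrence preserved.
#' @return object of class `target_set` (a list with `name`, `genes`).
#' @export
target_set <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop("target set '", name, "' is empty")
  if (anyDuplicated(genes)) {
    warning(sprintf("target set '%s': %d duplicate member(s) collapsed",
                    name, sum(duplicated(genes))))
    genes <- genes[!duplicated(genes)]
  }
  structure(list(name = as.character(name), genes = genes),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read gene target sets from GMT or plain list files
#'
#' GMT: one set per line, `name<TAB>description<TAB>member1<TAB>member2...`.
#' List: one gene per line; the set is named after the file.
#'
#' @param path file path.
#' @param format `"gmt"` or `"list"`.
#' @return a list of [target_set] objects.
#' @export
read_target_sets <- function(path, format = c("gmt", "list")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "list") {
    nm <- sub("\\.[^.]*$", "", basename(path))
    return(list(target_set(nm, trimws(lines))))
  }
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT set '", f[1L], "' is empty (no members)")
    target_set(f[1L], f[-(1:2)])
  })
}

# canonical GWAS column names and accepted aliases (upper-cased match)
.gwas_aliases <- list(
  snp = c("SNP", "RSID", "ID", "MARKERNAME", "VARIANT_ID"),
  chr = c("CHR", "CHROM", "CHROMOSOME"),
  bp  = c("BP", "POS", "POSITION", "BASE_PAIR_LOCATION"),
  a1  = c("A1", "EA", "EFFECT_ALLELE", "ALT"),
  a2  = c("A2", "OA", "NEA", "OTHER_ALLELE", "REF"),
  beta = c("BETA", "B", "EFFECT"),
  se  = c("SE", "STANDARD_ERROR", "STDERR"),
  p   = c("P", "PVAL", "P_VALUE", "PVALUE"),
  eaf = c("EAF", "FRQ", "FREQ", "EFFECT_ALLELE_FREQUENCY", "MAF"),
  n   = c("N", "SAMPLESIZE", "SAMPLE_SIZE")
)

#' Read GWAS summary statistics
#'
#' Tab-delimited with a header row. Required columns (any accepted alias,
#' case-insensitive): SNP, A1, A2, BETA, SE, P. Optional: CHR, BP, EAF, N.
#' Rows violating the per-record invariants (`se > 0`, `p` in (0,1], `a1 !=
#' a2`, finite beta) are dropped and counted; `p = 0` is clamped to the
#' smallest positive double with a warning, since public summary files
#' contain underflowed p-values.
#'
#' @param path file path.
#' @param aliases optional named list extending the built-in column aliases.
#' @return a `gwas_table`: data.frame with columns `snp, chr, bp, a1, a2,
#'   beta, se, p, eaf, n` and attribute `n_dropped`.
#' @export
read_gwas <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  amap <- .gwas_aliases
  for (nm in names(aliases)) amap[[nm]] <- unique(c(aliases[[nm]], amap[[nm]]))
  up <- toupper(names(raw))
  pick <- function(field) {
    hit <- which(up %in% amap[[field]])
    if (length(hit)) raw[[hit[1L]]] else NULL
  }
  required <- c("snp", "a1", "a2", "beta", "se", "p")
  missing <- required[vapply(required, function(f) is.null(pick(f)), logical(1))]
  if (length(missing))
    stop("missing required column(s): ", paste(toupper(missing), collapse = ", "))

  tab <- data.frame(
    snp = as.character(pick("snp")),
    chr = if (!is.null(pick("chr"))) as.character(pick("chr")) else NA_character_,
    bp  = if (!is.null(pick("bp"))) as.integer(pick("bp")) else NA_integer_,
    a1  = toupper(as.character(pick("a1"))),
    a2  = toupper(as.character(pick("a2"))),
    beta = as.numeric(pick("beta")),
    se  = as.numeric(pick("se")),
    p   = as.numeric(pick("p")),
    eaf = if (!is.null(pick("eaf"))) as.numeric(pick("eaf")) else NA_real_,
    n   = if (!is.null(pick("n"))) as.numeric(pick("n")) else NA_real_,
    stringsAsFactors = FALSE
  )
  gwas_table(tab)
}

#' Validate a GWAS summary-statistics table
#'
#' Applies the per-record invariants of [read_gwas()] to an in-memory
#' data.frame (same canonical column names).
#'
#' @param tab data.frame with at least `snp, a1, a2, beta, se, p`.
#' @return validated `gwas_table` with attribute `n_dropped`.
#' @export
gwas_table <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  for (col in c("chr", "bp", "eaf", "n"))
    if (is.null(tab[[col]])) tab[[col]] <- NA
  zero_p <- !is.na(tab$p) & tab$p == 0
  if (any(zero_p)) {
    warning(sprintf("%d p-value(s) of 0 clamped to %.3g", sum(zero_p),
                    .Machine$double.xmin))
    tab$p[zero_p] <- .Machine$double.xmin
  }
  ok <- !is.na(tab$snp) & nzchar(tab$snp) &
    !is.na(tab$beta) & is.finite(tab$beta) &
    !is.na(tab$se) & tab$se > 0 &
    !is.na(tab$p) & tab$p > 0 & tab$p <= 1 &
    !is.na(tab$a1) & !is.na(tab$a2) & tab$a1 != tab$a2
  n_drop <- sum(!ok)
  tab <- tab[ok, c("snp", "chr", "bp", "a1", "a2", "beta", "se", "p",
                   "eaf", "n"), drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, n_dropped = n_drop, class = c("gwas_table", "data.frame"))
}

#' Write a GWAS table (or any result data.frame) as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' A flat key-value container carrying the seed, permutation counts and
#' algorithm thresholds for a pipeline run. With the seed fixed, every
#' stochastic stage of the pipeline is reproducible.
#'
#' @param seed integer RNG seed.
#' @param n_permutations permutation count for the proximity null.
#' @param out_dir output directory (`NULL` = no files written).
#' @param ... further named scalar parameters.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_permutations = 1000L, out_dir = NULL, ...) {
  structure(c(list(seed = as.integer(seed),
                   n_permutations = as.integer(n_permutations),
                   out_dir = out_dir), list(...)),
            class = "run_config")
}
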