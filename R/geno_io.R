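#' Read a GenePop genotype file
#'
#' Accepts the common GenePop dialect for diploid SSR data: a title line,
#' locus names (one per line or comma-separated on one line), and `pop`
#' blocks of `label , 001002 003004 ...` rows with 2- or 3-digit allele
#' codes. The all-zeros code marks a missing genotype. Files written by
#' [write_genepop()] carry locus motif lengths and per-locus allele-size
#' offsets in the title line and round-trip losslessly; for other files the
#' motif defaults to 2 bp and the dataset is flagged raw.
#'
#' @param path path to a `.gen` file.
#' @return a [genotype_dataset()].
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("malformed GenePop file: fewer than 3 lines")
  title <- lines[1L]

  is_pop <- function(x) grepl("^\\s*pop\\s*$", x, ignore.case = TRUE)
  first_pop <- which(vapply(lines, is_pop, logical(1)))[1L]
  if (is.na(first_pop))
    stop("malformed GenePop file: no 'pop' separator found")
  if (first_pop < 3L)
    stop("malformed GenePop header: 'pop' before any locus line (line ",
         first_pop, ")")

  locus_lines <- lines[2:(first_pop - 1L)]
  locus_names <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_names <- locus_names[nzchar(locus_names)]
  if (length(locus_names) == 0L)
    stop("malformed GenePop header: no locus names (line 2)")
  nloc <- length(locus_names)

  meta <- parse_genepop_title(title, nloc)

  pop_ids <- character(0)
  pops <- character(0); inds <- character(0)
  rows <- list()
  cur_pop <- 0L
  width <- NA_integer_
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (is_pop(ln)) { cur_pop <- cur_pop + 1L; next }
    if (!nzchar(trimws(ln))) next
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L)
      stop("malformed genotype line ", i, ": no comma separator")
    label <- trimws(parts[1L])
    toks <- strsplit(trimws(paste(parts[-1L], collapse = ",")), "\\s+")[[1L]]
    if (length(toks) != nloc)
      stop("line ", i, ": expected ", nloc, " genotype tokens, got ",
           length(toks))
    w <- unique(nchar(toks))
    if (length(w) != 1L || !(w %in% c(4L, 6L)))
      stop("line ", i, ": inconsistent allele-code width (",
           paste(w, collapse = "/"), "); expected uniform 4- or 6-digit codes")
    if (is.na(width)) width <- w
    if (w != width)
      stop("line ", i, ": allele-code width ", w,
           " differs from earlier width ", width)
    half <- width %/% 2L
    a1 <- as.integer(substr(toks, 1L, half))
    a2 <- as.integer(substr(toks, half + 1L, width))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop("line ", i, ": non-numeric allele code")
    if (any(xor(a1 == 0L, a2 == 0L)))
      stop("line ", i, ": half-missing genotype (one allele coded 0)")
    miss <- a1 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    if (grepl("|", label, fixed = TRUE)) {
      lab <- strsplit(label, "|", fixed = TRUE)[[1L]]
      pid <- lab[1L]; iid <- lab[2L]
    } else {
      pid <- paste0("pop_", cur_pop); iid <- label
    }
    geno <- integer(2L * nloc)
    geno[seq(1L, 2L * nloc, 2L)] <- a1
    geno[seq(2L, 2L * nloc, 2L)] <- a2
    rows[[length(rows) + 1L]] <- geno
    pops <- c(pops, pid); inds <- c(inds, iid)
    if (!(pid %in% pop_ids)) pop_ids <- c(pop_ids, pid)
  }
  if (length(rows) == 0L) stop("GenePop file contains no genotypes")
  alleles <- do.call(rbind, rows)
  # add back per-locus offsets recorded by write_genepop
  if (!is.null(meta$offsets)) {
    for (j in seq_len(nloc)) {
      cols <- locus_cols(j)
      alleles[, cols] <- alleles[, cols] + meta$offsets[j]
    }
  }
  loci <- data.frame(name = locus_names,
                     motif = if (is.null(meta$motifs)) 2L else meta$motifs)
  genotype_dataset(alleles, pops, inds, loci, populations = pop_ids,
                   raw = is.null(meta$motifs))
}

parse_genepop_title <- function(title, nloc) {
  out <- list(motifs = NULL, offsets = NULL)
  grab <- function(key) {
    m <- regmatches(title, regexec(paste0(key, "=([0-9,]+)"), title))[[1L]]
    if (length(m) < 2L) return(NULL)
    v <- as.integer(strsplit(m[2L], ",")[[1L]])
    if (length(v) != nloc) return(NULL)
    v
  }
  out$motifs <- grab("motifs")
  out$offsets <- grab("offsets")
  out
}

#' Write a GenePop genotype file
#'
#' Writes 3-digit allele codes. Loci whose allele sizes exceed 999 are
#' shifted by a per-locus offset (recorded in the title line along with
#' the motif lengths, so [read_genepop()] restores the original sizes).
#' Population and individual IDs are encoded as `pop|ind` labels.
#'
#' @param dataset a [genotype_dataset()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_genepop <- function(dataset, path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  counts <- table(factor(dataset$pop, levels = dataset$populations))
  if (any(counts == 0L))
    stop("GenePop forbids empty populations: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  nloc <- n_loci(dataset)
  offsets <- integer(nloc)
  shifted <- dataset$alleles
  for (j in seq_len(nloc)) {
    cols <- locus_cols(j)
    sz <- shifted[, cols]
    mx <- suppressWarnings(max(sz, na.rm = TRUE))
    if (is.finite(mx) && mx > 999L) {
      offsets[j] <- min(sz, na.rm = TRUE) - 1L
      sz <- sz - offsets[j]
      if (max(sz, na.rm = TRUE) > 999L)
        stop("locus ", dataset$loci$name[j],
             ": allele-size range too wide for 3-digit codes")
      shifted[, cols] <- sz
    }
  }
  title <- paste0("walnutpg export; motifs=",
                  paste(dataset$loci$motif, collapse = ","),
                  "; offsets=", paste(offsets, collapse = ","))
  out <- c(title, dataset$loci$name)
  for (p in dataset$populations) {
    out <- c(out, "pop")
    for (i in which(dataset$pop == p)) {
      g <- shifted[i, ]
      g[is.na(g)] <- 0L
      toks <- sprintf("%03d%03d", g[seq(1L, length(g), 2L)],
                      g[seq(2L, length(g), 2L)])
      out <- c(out, paste0(p, "|", dataset$ind[i], " , ",
                           paste(toks, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a population metadata table
#'
#' Delimited text (comma or tab) with a header; expects a population ID
#' column followed by latitude, longitude and elevation columns (matched by
#' name, case-insensitively), plus optional `country` and `n` columns.
#'
#' @param path path to a `.csv`/`.tsv` file.
#' @return data.frame with columns `id`, `lat`, `lon`, `elev` and any
#'   optional columns present.
#' @export
read_population_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) <= 1L) {
    warning("population table is empty: ", path)
    return(data.frame(id = character(0), lat = numeric(0),
                      lon = numeric(0), elev = numeric(0)))
  }
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  nm <- tolower(names(df))
  pick <- function(keys) {
    hit <- which(nm %in% keys)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  i_id <- pick(c("id", "population", "pop", "site")); if (is.na(i_id)) i_id <- 1L
  i_lat <- pick(c("lat", "latitude"))
  i_lon <- pick(c("lon", "long", "longitude"))
  i_el <- pick(c("elev", "elevation", "alt", "altitude"))
  if (is.na(i_lat) || is.na(i_lon))
    stop("population table must have latitude and longitude columns")
  out <- data.frame(id = as.character(df[[i_id]]),
                    lat = as.numeric(df[[i_lat]]),
                    lon = as.numeric(df[[i_lon]]),
                    elev = if (is.na(i_el)) NA_real_ else as.numeric(df[[i_el]]),
                    stringsAsFactors = FALSE)
  i_cc <- pick(c("country", "cc")); if (!is.na(i_cc)) out$country <- df[[i_cc]]
  i_n <- pick(c("n", "samples", "count")); if (!is.na(i_n)) out$n <- df[[i_n]]
  if (anyDuplicated(out$id))
    stop("duplicate population ID(s): ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  bad <- which(out$lat < -90 | out$lat > 90)
  if (length(bad))
    stop("latitude out of [-90, 90] for: ", paste(out$id[bad], collapse = ", "))
  bad <- which(out$lon < -180 | out$lon > 180)
  if (length(bad))
    stop("longitude out of [-180, 180] for: ",
         paste(out$id[bad], collapse = ", "))
  out
}

#' Read STRUCTURE run output files
#'
#' Parses the `Estimated Ln Prob of Data` line and the
#' `Inferred ancestry of individuals` block of STRUCTURE `_f` output files.
#' K is inferred from the number of membership columns.
#'
#' @param paths character vector of file paths.
#' @return list with one element per file: `list(K, lnprob, Q)` where `Q`
#'   is a numeric matrix (rows = entities, columns = clusters) with entity
#'   labels as rownames.
#' @export
read_structure_runs <- function(paths) {
  lapply(paths, read_structure_run)
}

read_structure_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lp_line <- grep("Estimated Ln Prob of Data", lines, value = TRUE)
  if (length(lp_line) == 0L)
    stop(path, ": no 'Estimated Ln Prob of Data' line")
  lnprob <- as.numeric(sub(".*=\\s*", "", lp_line[1L]))
  start <- grep("Inferred ancestry of individuals", lines)
  if (length(start) == 0L)
    stop(path, ": missing 'Inferred ancestry of individuals' block")
  i <- start[1L] + 1L
  # skip the column-header line if present
  if (i <= length(lines) && grepl("Label", lines[i])) i <- i + 1L
  labels <- character(0); qrows <- list()
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    ln <- lines[i]
    halves <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(halves) != 2L)
      stop(path, " line ", i, ": malformed ancestry row")
    left <- strsplit(trimws(halves[1L]), "\\s+")[[1L]]
    q <- as.numeric(strsplit(trimws(halves[2L]), "\\s+")[[1L]])
    if (any(is.na(q)))
      stop(path, " line ", i, ": non-numeric membership value")
    if (abs(sum(q) - 1) > 1e-3)
      stop(path, " line ", i, ": Q row sums to ", format(sum(q)),
           ", outside 1 +/- 1e-3")
    labels <- c(labels, left[2L])
    qrows[[length(qrows) + 1L]] <- q
    i <- i + 1L
  }
  if (length(qrows) == 0L) stop(path, ": empty ancestry block")
  K <- unique(vapply(qrows, length, integer(1)))
  if (length(K) != 1L)
    stop(path, ": rows disagree on the number of clusters")
  Q <- do.call(rbind, qrows)
  rownames(Q) <- labels
  list(K = K, lnprob = lnprob, Q = Q)
}

#' Write a tree in newick format
#'
#' @param tree an `ape` `phylo` object with labelled tips.
#' @param path output path (`.nwk`).
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labelled")
  ape::write.tree(tree, file = path)
  invisible(path)
}
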