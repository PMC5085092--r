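# The population reference graph: a leveled DAG with single-character edges.
#
# Levels correspond to columns of the merged gene alignment; adjacent levels
# are joined by one edge per distinct character observed in that column, so
# identical characters shared by several alleles are collapsed onto the same
# edge. '-' edges are graph-encoded gaps (zero read width); 'N' edges are
# literal wildcard bases (spacers between genes, or rare wildcards in input
# alleles). Each allele is recorded as one or more coverage runs of edge
# labels; for alleles present in all segments the run is a full
# source-to-sink path.

#' Build a gene PRG from a segmented gene alignment
#'
#' One level per alignment column; one edge per distinct character per column.
#'
#' @param seg a `prg_segmented_gene` from [merge_blocks()] / [build_gene_msa()].
#' @param pbs_exons integer vector of exon numbers forming the peptide-binding
#'   site for this locus (class I-like loci: `c(2, 3)`; class II-like: `2`).
#' @return an object of class `prg`.
#' @export
build_gene_graph <- function(seg, pbs_exons = c(2L, 3L)) {
  stopifnot(inherits(seg, "prg_segmented_gene"))
  mat <- seg$mat
  n_levels <- ncol(mat)
  edges <- lapply(seq_len(n_levels), function(j) {
    v <- mat[, j]
    sort(unique(v[!is.na(v)]))
  })
  if (any(lengths(edges) == 0L))
    stop("alignment column with no covering allele at level ",
         which(lengths(edges) == 0L)[1L])
  paths <- lapply(rownames(mat), function(id) {
    covered <- !is.na(mat[id, ])
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- list()
    for (i in seq_along(r$values)) {
      if (r$values[i])
        runs[[length(runs) + 1L]] <- list(start = starts[i],
                                          labels = mat[id, starts[i]:ends[i]])
    }
    runs
  })
  names(paths) <- rownames(mat)
  features <- seg$features %||% rep(NA_character_, n_levels)
  pbs_feats <- paste0("exon_", pbs_exons)
  pbs_levels <- which(features %in% pbs_feats)
  loci <- data.frame(level = seq_len(n_levels),
                     locus = rep(seg$locus, n_levels),
                     feature = features,
                     stringsAsFactors = FALSE)
  prg <- structure(
    list(n_levels = n_levels,
         edges = edges,
         loci = loci,
         paths = paths,
         alleles = data.frame(allele_id = rownames(mat),
                              locus = rep(seg$locus, nrow(mat)),
                              stringsAsFactors = FALSE),
         pbs = setNames(list(as.integer(pbs_levels)), seg$locus)),
    class = "prg"
  )
  prg
}

#' Concatenate gene PRGs into a joint PRG with N spacers
#'
#' Genes are concatenated in input order; consecutive genes are separated by a
#' linear run of `spacer_length` 'N'-labelled edges, which prevents k-mers and
#' alignments from crossing gene boundaries.
#'
#' @param gene_prgs list of `prg` objects.
#' @param spacer_length number of 'N' spacer levels between consecutive genes
#'   (default 2000; 0 gives direct concatenation).
#' @return a joint `prg`.
#' @export
build_joint_prg <- function(gene_prgs, spacer_length = 2000L) {
  if (length(gene_prgs) == 0L) stop("empty gene list")
  stopifnot(all(vapply(gene_prgs, inherits, logical(1), "prg")),
            spacer_length >= 0L)
  edges <- list(); loci <- list(); paths <- list(); alleles <- list(); pbs <- list()
  offset <- 0L
  for (i in seq_along(gene_prgs)) {
    g <- gene_prgs[[i]]
    if (i > 1L && spacer_length > 0L) {
      edges <- c(edges, rep(list("N"), spacer_length))
      loci[[length(loci) + 1L]] <- data.frame(
        level = offset + seq_len(spacer_length),
        locus = "spacer", feature = "spacer", stringsAsFactors = FALSE)
      offset <- offset + as.integer(spacer_length)
    }
    edges <- c(edges, g$edges)
    gl <- g$loci; gl$level <- gl$level + offset
    loci[[length(loci) + 1L]] <- gl
    shifted <- lapply(g$paths, function(runs) lapply(runs, function(r) {
      r$start <- r$start + offset; r
    }))
    paths <- c(paths, shifted)
    alleles[[length(alleles) + 1L]] <- g$alleles
    pbs <- c(pbs, lapply(g$pbs, function(v) v + offset))
    offset <- offset + g$n_levels
  }
  structure(
    list(n_levels = offset, edges = edges,
         loci = do.call(rbind, loci), paths = paths,
         alleles = do.call(rbind, alleles), pbs = pbs),
    class = "prg"
  )
}

#' @export
print.prg <- function(x, ...) {
  cat(sprintf("<prg> %d levels, %d edges, %d alleles, loci: %s\n",
              x$n_levels, sum(lengths(x$edges)), length(x$paths),
              paste(names(x$pbs), collapse = ", ")))
  invisible(x)
}

#' Reconstruct an allele's un-gapped sequence from its PRG path
#' @param prg a `prg`.
#' @param allele allele id.
#' @return un-gapped sequence string.
#' @export
allele_path_sequence <- function(prg, allele) {
  runs <- prg$paths[[allele]]
  if (is.null(runs)) stop("unknown allele: ", allele)
  chars_str(unlist(lapply(runs, function(r) r$labels[r$labels != "-"])))
}

# label of an allele at a given level, NA if the allele does not cover it
allele_label_at <- function(runs, levels) {
  out <- rep(NA_character_, length(levels))
  for (r in runs) {
    idx <- levels - r$start + 1L
    inside <- idx >= 1L & idx <= length(r$labels)
    out[inside] <- r$labels[idx[inside]]
  }
  out
}

#' Peptide-binding-site genotypes and G groups for a locus
#'
#' For each allele at the locus, the ordered sequence of edge labels
#' (including `-`) that its path takes through the PBS levels. Alleles with
#' identical PBS genotype strings form one G group, named after the
#' lexicographically smallest member with a `"G"` suffix.
#'
#' @param prg a `prg`.
#' @param locus gene name present in the PRG.
#' @return a list with `genotypes` (named character vector, allele ->
#'   PBS genotype string), `group_of` (named character vector, allele ->
#'   G group name) and `groups` (named list, G group -> member alleles).
#' @export
allele_pbs_genotypes <- function(prg, locus) {
  stopifnot(inherits(prg, "prg"))
  if (!locus %in% names(prg$pbs)) stop("locus not in PRG: ", locus)
  levels <- prg$pbs[[locus]]
  if (length(levels) == 0L) stop("no PBS levels defined for locus ", locus)
  ids <- prg$alleles$allele_id[prg$alleles$locus == locus]
  genotypes <- vapply(ids, function(id) {
    lab <- allele_label_at(prg$paths[[id]], levels)
    if (anyNA(lab))
      stop("allele '", id, "' does not traverse all PBS levels of locus ",
           locus, " (malformed graph)")
    chars_str(lab)
  }, character(1))
  members <- split(ids, genotypes[ids])
  reps <- vapply(members, function(m) paste0(min(m), "G"), character(1))
  groups <- setNames(members, reps)
  groups <- groups[order(names(groups))]
  group_of <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  list(genotypes = genotypes, group_of = group_of[ids], groups = groups)
}

# ---- serialization ----------------------------------------------------------

#' Write a PRG to its versioned text format (plus JSON sidecar)
#'
#' The text format has a header line, one `E` line per edge
#' (`level  from_node  to_node  label`), one `P` line per allele coverage run,
#' an `L` locus/feature annotation block (run-length encoded) and `A` lines
#' mapping alleles to loci. PBS levels go to a `<path>.pbs.json` sidecar.
#' All coordinates are 1-based. The round trip through [read_prg()] is
#' lossless.
#'
#' @param prg a `prg`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_prg <- function(prg, path) {
  stopifnot(inherits(prg, "prg"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  lines <- c(sprintf("PRG\t1\t%d", prg$n_levels))
  for (l in seq_len(prg$n_levels)) {
    for (lab in prg$edges[[l]])
      lines <- c(lines, sprintf("E\t%d\tn%d\tn%d\t%s", l, l - 1L, l, lab))
  }
  for (id in names(prg$paths)) {
    for (r in prg$paths[[id]])
      lines <- c(lines, sprintf("P\t%s\t%d\t%s", id, r$start,
                                chars_str(r$labels)))
  }
  key <- paste(prg$loci$locus, prg$loci$feature, sep = "\r")
  rl <- rle(key)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  parts <- strsplit(rl$values, "\r", fixed = TRUE)
  for (i in seq_along(rl$values))
    lines <- c(lines, sprintf("L\t%d\t%d\t%s\t%s", starts[i], ends[i],
                              parts[[i]][1L], parts[[i]][2L]))
  for (i in seq_len(nrow(prg$alleles)))
    lines <- c(lines, sprintf("A\t%s\t%s", prg$alleles$allele_id[i],
                              prg$alleles$locus[i]))
  writeLines(lines, con)
  jsonlite::write_json(prg$pbs, paste0(path, ".pbs.json"))
  invisible(path)
}

#' Read a PRG from its text format
#' @param path file written by [write_prg()].
#' @return a `prg`.
#' @export
read_prg <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "PRG\t"))
    stop("not a PRG file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  n_levels <- as.integer(header[3L])
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  tag <- vapply(fields, `[`, character(1), 1L)

  edges <- rep(list(character(0)), n_levels)
  for (f in fields[tag == "E"]) {
    l <- as.integer(f[2L])
    edges[[l]] <- c(edges[[l]], f[5L])
  }
  edges <- lapply(edges, sort)

  paths <- list()
  for (f in fields[tag == "P"]) {
    id <- f[2L]
    run <- list(start = as.integer(f[3L]), labels = str_chars(f[4L]))
    paths[[id]] <- c(paths[[id]], list(run))
  }

  lrows <- fields[tag == "L"]
  loci <- data.frame(level = seq_len(n_levels),
                     locus = NA_character_, feature = NA_character_,
                     stringsAsFactors = FALSE)
  for (f in lrows) {
    idx <- as.integer(f[2L]):as.integer(f[3L])
    loci$locus[idx] <- if (f[4L] == "NA") NA_character_ else f[4L]
    loci$feature[idx] <- if (f[5L] == "NA") NA_character_ else f[5L]
  }

  arows <- fields[tag == "A"]
  alleles <- data.frame(
    allele_id = vapply(arows, `[`, character(1), 2L),
    locus = vapply(arows, `[`, character(1), 3L),
    stringsAsFactors = FALSE)

  sidecar <- paste0(path, ".pbs.json")
  pbs <- if (file.exists(sidecar)) {
    lapply(jsonlite::read_json(sidecar), function(v) as.integer(unlist(v)))
  } else list()

  structure(list(n_levels = n_levels, edges = edges, loci = loci,
                 paths = paths[unique(alleles$allele_id)],
                 alleles = alleles, pbs = pbs),
            class = "prg")
}

# ---- compact edge representation for the alignment core ---------------------

# CSR-style view consumed by the C++ dynamic programming kernel:
# lab[ptr[l]+1 .. ptr[l+1]] are the integer edge codes of level l (1-based).
prg_csr <- function(prg) {
  nl <- prg$n_levels
  counts <- lengths(prg$edges)
  ptr <- c(0L, cumsum(counts))
  lab <- encode_bases(unlist(prg$edges, use.names = FALSE))
  spacer <- !is.na(prg$loci$feature) & prg$loci$feature == "spacer"
  list(ptr = as.integer(ptr), lab = as.integer(lab), n_levels = nl,
       spacer = spacer)
}

#' Enumerate all source-to-sink path sequences of a PRG (testing oracle)
#'
#' Expands the Cartesian product of edge labels over levels, removes graph
#' gaps and deduplicates. Only usable on small graphs; guarded by `max_paths`.
#'
#' @param prg a `prg`.
#' @param max_paths abort if the number of label combinations exceeds this.
#' @return character vector of distinct un-gapped path sequences.
#' @export
enumerate_path_sequences <- function(prg, max_paths = 1e4) {
  n_paths <- prod(lengths(prg$edges))
  if (n_paths > max_paths)
    stop("graph has ", n_paths, " source-to-sink paths; refusing to enumerate")
  seqs <- ""
  for (l in seq_len(prg$n_levels)) {
    labs <- prg$edges[[l]]
    labs[labs == "-"] <- ""
    seqs <- as.vector(outer(seqs, labs, paste0))
    seqs <- unique(seqs)
  }
  unique(seqs)
}
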