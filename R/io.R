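# Readers and writers for the exchanged plain-text formats, and merging of
# independently produced frequency datasets.

write_tsv_prov <- function(x, path, seed = NULL) {
  writeLines(sprintf("# written by poolgsi %s on %s%s",
                     as.character(utils::packageVersion("poolgsi")),
                     format(Sys.time(), "%Y-%m-%d"),
                     if (is.null(seed)) "" else sprintf("; seed %d", seed)),
             path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write a population allele-frequency table
#'
#' The interchange format is a TSV with a `locus` column followed by one
#' numeric column per population, values in \[0, 1\], optionally preceded by
#' `#` provenance comment lines. Duplicate loci and out-of-range values are
#' rejected with the offending cell named.
#'
#' @param path File path.
#'
#' @return `read_freq_table()`: wide frequency tibble.
#' @export
read_freq_table <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"locus" %in% names(x)) abort("frequency table needs a `locus` column")
  x$locus <- as.character(x$locus)
  if (anyDuplicated(x$locus)) {
    abort(sprintf("duplicate locus id '%s'", x$locus[duplicated(x$locus)][1]))
  }
  freq_matrix(x)  # validates range, names the offending cell
  x
}

#' @rdname read_freq_table
#' @param freqs Wide frequency tibble.
#' @param seed Optional seed recorded in the provenance header.
#' @return `write_freq_table()`: the path, invisibly.
#' @export
write_freq_table <- function(freqs, path, seed = NULL) {
  freq_matrix(freqs)
  write_tsv_prov(freqs, path, seed)
}

#' Read / write replicate pool thetas
#'
#' Long TSV with columns `population`, `locus`, `replicate`, `theta`.
#'
#' @param path File path.
#' @return `read_theta_replicates()`: long replicate tibble.
#' @export
read_theta_replicates <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_theta_long(x)
  x
}

#' @rdname read_theta_replicates
#' @param thetas Long replicate tibble.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_theta_replicates <- function(thetas, path, seed = NULL) {
  check_theta_long(thetas)
  write_tsv_prov(thetas, path, seed)
}

#' Read a genotype-cluster reference table
#'
#' TSV with columns `locus`, `theta_AA`, `theta_AB`, `theta_BB`; the strict
#' AA < AB < BB ordering is validated per locus.
#'
#' @param path File path.
#' @return Cluster-reference tibble.
#' @export
read_cluster_reference <- function(path) {
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("locus", "theta_AA", "theta_AB", "theta_BB")
  if (!all(need %in% names(x))) {
    abort("cluster reference needs columns locus, theta_AA, theta_AB, theta_BB")
  }
  bad <- which(x$theta_AA >= x$theta_AB | x$theta_AB >= x$theta_BB)
  if (length(bad)) {
    abort(sprintf("cluster thetas not strictly ordered at locus '%s'",
                  x$locus[bad[1]]))
  }
  x
}

#' Read / write genotypes in Genepop format
#'
#' Two-digit biallelic coding (allele 01 = A, 02 = B), one locus name per
#' line after the title, population blocks introduced by `POP` lines,
#' individuals as `name , 0101 0102 ...`. Only complete biallelic records
#' are accepted; missing-genotype tokens (`0000`) and third alleles are
#' rejected.
#'
#' @param path File path.
#' @return `read_genepop()`: a `genotypes` object whose `origin` holds the
#'   name of the first individual of each population block (the Genepop
#'   convention for labelling populations).
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) abort("not a Genepop file: too short")
  body <- lines[-1]
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) abort("not a Genepop file: no POP line")
  loci <- trimws(body[seq_len(first_pop - 1)])
  if (length(loci) == 1 && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  geno_rows <- list()
  origins <- character(0)
  inds <- character(0)
  pop_label <- NA_character_
  for (ln in body[first_pop:length(body)]) {
    if (toupper(trimws(ln)) == "POP") {
      pop_label <- NA_character_
      next
    }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) != 2) abort(sprintf("malformed Genepop record: '%s'", ln))
    ind <- trimws(parts[1])
    toks <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(toks) != length(loci)) {
      abort(sprintf("individual '%s' has %d genotypes for %d loci",
                    ind, length(toks), length(loci)))
    }
    if (is.na(pop_label)) pop_label <- ind
    g <- vapply(toks, function(tk) {
      if (nchar(tk) != 4) abort(sprintf("bad genotype token '%s' for '%s'", tk, ind))
      a1 <- substr(tk, 1, 2)
      a2 <- substr(tk, 3, 4)
      if (a1 == "00" || a2 == "00") {
        abort(sprintf("missing genotype '%s' for '%s': complete data required", tk, ind))
      }
      if (!a1 %in% c("01", "02") || !a2 %in% c("01", "02")) {
        abort(sprintf("allele outside biallelic coding in '%s' for '%s'", tk, ind))
      }
      (a1 == "02") + (a2 == "02")
    }, integer(1), USE.NAMES = FALSE)
    geno_rows[[length(geno_rows) + 1]] <- g
    origins <- c(origins, pop_label)
    inds <- c(inds, ind)
  }
  geno <- do.call(rbind, geno_rows)
  dimnames(geno) <- list(inds, loci)
  structure(list(geno = geno, origin = origins, role = "baseline"),
            class = "genotypes")
}

#' @rdname read_genepop
#' @param genotypes A `genotypes` object.
#' @param title Title line written as the first file line.
#' @export
write_genepop <- function(genotypes, path, title = "poolgsi export") {
  stopifnot(inherits(genotypes, "genotypes"))
  g <- genotypes$geno
  code <- c(`0` = "0101", `1` = "0102", `2` = "0202")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(colnames(g), con)
  for (pop in unique(genotypes$origin)) {
    writeLines("POP", con)
    for (i in which(genotypes$origin == pop)) {
      writeLines(paste0(rownames(g)[i], " , ",
                        paste(code[as.character(g[i, ])], collapse = " ")),
                 con)
    }
  }
  invisible(path)
}

#' Merge two allele-frequency datasets on shared loci
#'
#' Joins two frequency tables on their locus intersection and takes the
#' population union, harmonising allele orientation: for loci named in
#' `flip`, the second table's frequencies are replaced by `1 - p` before
#' merging. Nothing is reoriented silently; the merge report lists every
#' flip applied and every locus dropped from either side. Overlapping
#' population names take the first table's values.
#'
#' @param a,b Wide frequency tibbles.
#' @param flip Character vector of loci whose B allele is labelled
#'   oppositely in `b` (may be empty).
#'
#' @return List with `merged` (wide tibble on shared loci; empty tibble if
#'   the locus sets are disjoint) and `report` (list: `n_shared`,
#'   `dropped_a`, `dropped_b`, `flipped`, `duplicate_pops`).
#' @export
merge_frequency_datasets <- function(a, b, flip = character(0)) {
  ma <- freq_matrix(a)
  mb <- freq_matrix(b)
  unknown <- setdiff(flip, rownames(mb))
  if (length(unknown)) {
    abort(paste0("flip lists loci absent from b: ", toString(unknown)))
  }
  shared <- intersect(rownames(ma), rownames(mb))
  flipped <- intersect(flip, shared)
  dup <- intersect(colnames(ma), colnames(mb))
  report <- list(n_shared = length(shared),
                 dropped_a = setdiff(rownames(ma), shared),
                 dropped_b = setdiff(rownames(mb), shared),
                 flipped = flipped,
                 duplicate_pops = dup)
  if (!length(shared)) {
    return(list(merged = tibble::tibble(locus = character(0)),
                report = report))
  }
  mb <- mb[shared, , drop = FALSE]
  mb[flipped, ] <- 1 - mb[flipped, ]
  merged <- cbind(ma[shared, , drop = FALSE],
                  mb[, setdiff(colnames(mb), dup), drop = FALSE])
  list(merged = freq_tibble(merged), report = report)
}
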