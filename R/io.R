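#' Read and write poset files
#'
#' Tab-separated poset exchange format. Each gene block opens with a species
#' header line `#species<TAB>s1,s2,...` declaring the ground set (so species
#' incomparable to everything but the focal species are representable), and
#' is followed by data lines `gene<TAB>focal<TAB>lesser<TAB>greater`, one
#' strict pair per line, meaning `lesser` is strictly closer to `focal` than
#' `greater` is. Other lines starting with `#` are comments. Species labels
#' match `[A-Za-z0-9_.-]+`. Pairs may be cover (Hasse) edges or the full
#' relation: transitive closure is applied on read, and missing
#' focal-minimum pairs are auto-completed with a notice. Writing emits the
#' full strict relation, so write-then-read is the identity.
#'
#' @param path File path.
#' @return `read_poset_file`: a named list of [poset_family()] objects, one
#'   per gene.
#' @export
read_poset_file <- function(path) {
  if (!file.exists(path)) {
    phgt_stop(paste0("no such file: ", path), "parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  species_for_gene <- list()
  rows <- list()
  current_species <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "#")) {
      if (startsWith(line, "#species\t")) {
        current_species <- strsplit(sub("^#species\t", "", line), ",",
                                    fixed = TRUE)[[1L]]
        current_species <- trimws(current_species)
      }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 4L) {
      phgt_stop(sprintf("line %d: expected 4 tab-separated fields, got %d",
                        ln, length(fields)), "parse_error")
    }
    if (is.null(current_species)) {
      phgt_stop(sprintf("line %d: data before any #species header", ln),
                "parse_error")
    }
    gene <- fields[1L]
    if (is.null(species_for_gene[[gene]])) {
      species_for_gene[[gene]] <- current_species
    }
    bad <- setdiff(fields[2:4], species_for_gene[[gene]])
    if (length(bad) > 0L) {
      phgt_stop(sprintf("line %d: unknown species label(s): %s",
                        ln, paste(bad, collapse = ", ")), "parse_error")
    }
    if (fields[3L] == fields[4L]) {
      phgt_stop(sprintf("line %d: reflexive pair (%s,%s)",
                        ln, fields[3L], fields[4L]),
                "parse_error")
    }
    rows[[length(rows) + 1L]] <- fields
  }
  if (length(rows) == 0L) {
    phgt_stop("no poset data lines found", "parse_error")
  }
  tab <- do.call(rbind, rows)
  families <- list()
  for (gene in unique(tab[, 1L])) {
    sp <- species_for_gene[[gene]]
    gtab <- tab[tab[, 1L] == gene, , drop = FALSE]
    posets <- lapply(sp, function(focal) {
      sel <- gtab[gtab[, 2L] == focal, c(3L, 4L), drop = FALSE]
      tryCatch(poset(focal, sel, sp),
               antisymmetry_violation = function(e) {
                 phgt_stop(sprintf(
                   "gene '%s', focal '%s': %s", gene, focal,
                   conditionMessage(e)), "parse_error")
               })
    })
    families[[gene]] <- poset_family(gene, posets, sp)
  }
  families
}

#' @rdname read_poset_file
#' @param families A named list of [poset_family()] objects (or a single
#'   one).
#' @export
write_poset_file <- function(families, path) {
  if (inherits(families, "poset_family")) families <- list(families)
  out <- character(0)
  for (fam in families) {
    out <- c(out, paste0("#species\t", paste(sort(fam$species),
                                             collapse = ",")))
    for (p in fam$posets) {
      if (nrow(p$pairs) > 0L) {
        out <- c(out, paste(fam$gene, p$focal,
                            p$pairs[, 1L], p$pairs[, 2L], sep = "\t"))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

# Matrix TSV: header of labels, integer rows, diagonal as -1.
write_matrix_tsv <- function(a, path) {
  labs <- rownames(a)
  body <- apply(unclass_matrix(a), 1L, paste, collapse = "\t")
  writeLines(c(paste(c("", labs), collapse = "\t"),
               paste(labs, body, sep = "\t")),
             path)
  invisible(path)
}
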