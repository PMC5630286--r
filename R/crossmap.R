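# Cross-species ortholog mapping and the human mutation catalog.
#
# Mouse gene symbols are converted to human ortholog symbols via an
# orthology table; mutation positions are lifted through a local
# (affine-gap) mRNA-vs-mRNA alignment; and the human medulloblastoma
# mutation catalog — one cell per gene and study in the compact
# "SUBGROUPS (TOTAL: TYPELIST)" notation — is parsed into typed entries
# for concordance and tally computations. Catalog type letters (M, N, F,
# S, D) are opaque codes; only the loss-of-function {N, F} and missense
# {M} letter sets are given semantics, and both are configurable.

#' Read an ortholog table
#'
#' @param path TSV with columns mouse_symbol, human_symbol and optionally
#'   mouse_mrna, human_mrna.
#' @return data.table; duplicate mouse symbols are a configuration error.
#' @export
read_ortholog_table <- function(path) {
  tbl <- fread(path, sep = "\t", colClasses = "character")
  if (anyDuplicated(tbl$mouse_symbol))
    stop("read_ortholog_table: duplicate mouse symbols in ", path)
  tbl
}

#' Map mouse gene symbols to human ortholog symbols
#'
#' Exact-match lookup, falling back to case-normalized comparison (mouse
#' title-case vs human upper-case); absent symbols return NA.
#'
#' @param symbols character vector of mouse symbols.
#' @param tbl ortholog table ([read_ortholog_table()]).
#' @return character vector of human symbols (NA when unmapped).
#' @export
map_ortholog <- function(symbols, tbl) {
  if (anyDuplicated(tbl$mouse_symbol))
    stop("map_ortholog: duplicate mouse symbols in ortholog table")
  hit <- match(symbols, tbl$mouse_symbol)
  miss <- is.na(hit)
  if (any(miss)) hit[miss] <- match(toupper(symbols[miss]),
                                    toupper(tbl$mouse_symbol))
  out <- tbl$human_symbol[hit]
  if (any(is.na(out)))
    message("map_ortholog: no ortholog for ",
            paste(unique(symbols[is.na(out)]), collapse = ", "))
  out
}

#' Local mRNA alignment with a coordinate map
#'
#' Aligns the mouse mRNA to its human ortholog mRNA (local alignment,
#' affine gaps; defaults match +2 / mismatch -3 / gap open 5 / gap extend
#' 2) and walks the traceback into a column-by-column position map. Below
#' `score_floor` the pair is reported unmapped.
#'
#' @param mouse_seq,human_seq nucleotide sequences (character).
#' @param scoring an [align_scoring()] list.
#' @param score_floor minimum alignment score to accept a map.
#' @return list: `aligned` (logical), `score`, and `map` — a
#'   data.table(mouse_pos, human_pos) over aligned (non-gap) columns.
#' @export
align_mrna <- function(mouse_seq, human_seq, scoring = align_scoring(),
                       score_floor = 40) {
  if (!nchar(mouse_seq) || !nchar(human_seq))
    stop("align_mrna: sequences must be nonempty")
  pa <- pairwise_local(mouse_seq, human_seq, scoring)
  sc <- BiocGenerics::score(pa)
  empty <- data.table(mouse_pos = integer(), human_pos = integer())
  if (sc < score_floor)
    return(list(aligned = FALSE, score = sc, map = empty))
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  mp <- IRanges::start(Biostrings::pattern(pa)) - 1L
  hp <- IRanges::start(Biostrings::subject(pa)) - 1L
  n <- length(ap)
  mouse_pos <- integer(n); human_pos <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    if (ap[i] != "-") mp <- mp + 1L
    if (as_[i] != "-") hp <- hp + 1L
    if (ap[i] != "-" && as_[i] != "-") {
      mouse_pos[i] <- mp; human_pos[i] <- hp; keep[i] <- TRUE
    }
  }
  list(aligned = TRUE, score = sc,
       map = data.table(mouse_pos = mouse_pos[keep],
                        human_pos = human_pos[keep]))
}

#' Lift a mutation position through an mRNA alignment
#'
#' @param mouse_pos 1-based position on the mouse mRNA (CDS coordinates
#'   when codon numbering is wanted).
#' @param alignment result of [align_mrna()].
#' @return list: `mapped` (logical), `human_pos`, `human_codon`
#'   (= ceiling(human_pos / 3)); unmapped when the alignment failed or the
#'   position falls in an unaligned gap or tail.
#' @export
lift_mutation <- function(mouse_pos, alignment) {
  if (!isTRUE(alignment$aligned))
    return(list(mapped = FALSE, human_pos = NA_integer_,
                human_codon = NA_integer_))
  i <- match(mouse_pos, alignment$map$mouse_pos)
  if (is.na(i))
    return(list(mapped = FALSE, human_pos = NA_integer_,
                human_codon = NA_integer_))
  hp <- alignment$map$human_pos[i]
  list(mapped = TRUE, human_pos = hp,
       human_codon = as.integer(ceiling(hp / 3)))
}

#' Parse one catalog cell
#'
#' Grammar: `SUBGROUPS (TOTAL: TYPELIST)` with SUBGROUPS a comma-separated
#' list of WNT/SHH/G3/G4/U, and TYPELIST comma-separated `LETTER[COUNT]`
#' tokens where an absent COUNT means 1; `-` (or empty) is an empty entry.
#' A cell whose total disagrees with the sum of its type counts is a parse
#' error naming the cell.
#'
#' @param text one catalog cell.
#' @return NULL for an empty cell, else list(subgroups, total, types
#'   (named integer vector by letter)).
#' @export
parse_catalog_entry <- function(text) {
  s <- trimws(text)
  if (s == "-" || s == "") return(NULL)
  m <- regmatches(s, regexec(
    "^([A-Z0-9]+(?:,[A-Z0-9]+)*)\\s*\\((\\d+):\\s*([A-Z]\\d*(?:,\\s*[A-Z]\\d*)*)\\)$",
    s))[[1]]
  if (!length(m)) stop("parse_catalog_entry: cannot parse cell '", text, "'")
  subgroups <- strsplit(m[2], ",", fixed = TRUE)[[1]]
  total <- as.integer(m[3])
  toks <- trimws(strsplit(m[4], ",", fixed = TRUE)[[1]])
  letters_ <- substr(toks, 1L, 1L)
  counts <- suppressWarnings(as.integer(substring(toks, 2L)))
  counts[is.na(counts)] <- 1L
  types <- tapply(counts, letters_, sum)
  types <- setNames(as.integer(types), names(types))
  if (sum(types) != total)
    stop("parse_catalog_entry: total ", total, " != sum of type counts ",
         sum(types), " in cell '", text, "'")
  list(subgroups = sort(subgroups), total = total,
       types = types[order(names(types))])
}

#' Canonical text form of a catalog entry
#'
#' @param entry a [parse_catalog_entry()] result (NULL gives "-").
#' @return character cell whose re-parse equals the entry (idempotent
#'   normalization).
#' @export
format_catalog_entry <- function(entry) {
  if (is.null(entry)) return("-")
  toks <- ifelse(entry$types == 1L, names(entry$types),
                 paste0(names(entry$types), entry$types))
  sprintf("%s (%d: %s)", paste(sort(entry$subgroups), collapse = ","),
          entry$total, paste(toks, collapse = ","))
}

#' Read a mutation catalog
#'
#' @param path catalog TSV: a `gene` column plus one column per study, each
#'   cell in the catalog notation.
#' @param studies_path TSV(study, species, n) with cohort sizes; column
#'   names of the catalog (besides `gene`) must match its study ids.
#' @return object of class `mutation_catalog`: `entries`
#'   (data.table: gene, study, subgroups list, total, types list) and
#'   `studies`.
#' @export
read_mutation_catalog <- function(path, studies_path) {
  raw <- fread(path, sep = "\t", colClasses = "character")
  studies <- fread(studies_path, sep = "\t",
                   colClasses = list(character = c("study", "species")))
  if (any(studies$n <= 0)) stop("read_mutation_catalog: cohort sizes must be positive")
  study_cols <- setdiff(names(raw), "gene")
  missing <- setdiff(study_cols, studies$study)
  if (length(missing))
    stop("read_mutation_catalog: studies file lacks: ",
         paste(missing, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(raw))) {
    for (st in study_cols) {
      e <- tryCatch(parse_catalog_entry(raw[[st]][i]),
                    error = function(err) stop(
                      "read_mutation_catalog: gene ", raw$gene[i], ", study ",
                      st, ": ", conditionMessage(err)))
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <- data.table(
        gene = raw$gene[i], study = st, total = e$total,
        subgroups = list(e$subgroups), types = list(e$types))
    }
  }
  entries <- if (length(rows)) rbindlist(rows) else
    data.table(gene = character(), study = character(), total = integer(),
               subgroups = list(), types = list())
  structure(list(entries = entries, studies = studies,
                 genes = unique(raw$gene)),
            class = "mutation_catalog")
}

human_entries <- function(catalog) {
  hs <- catalog$studies$study[catalog$studies$species == "human"]
  catalog$entries[study %in% hs]
}

#' Mouse-side records embedded in a catalog
#'
#' @param catalog a [read_mutation_catalog()] result containing a
#'   mouse-species study column.
#' @return data.table(gene, subgroup) with one row per mouse entry
#'   subgroup.
#' @export
catalog_mouse_records <- function(catalog) {
  ms <- catalog$studies$study[catalog$studies$species == "mouse"]
  e <- catalog$entries[study %in% ms]
  if (!nrow(e)) return(data.table(gene = character(), subgroup = character()))
  rbindlist(lapply(seq_len(nrow(e)), function(i)
    data.table(gene = e$gene[i], subgroup = e$subgroups[[i]])))
}

#' Genes whose mouse mutation subgroup recurs in a human study
#'
#' A gene is concordant iff some mouse record's subgroup label appears
#' among the subgroup labels of at least one human study entry for that
#' gene. Matching is on subgroup only (not mutation-type letter).
#'
#' @param mouse_records data.table(gene, subgroup) of mouse mutations
#'   (human ortholog symbols).
#' @param catalog a `mutation_catalog`.
#' @return sorted character vector of concordant genes.
#' @export
subgroup_concordant_genes <- function(mouse_records, catalog) {
  he <- human_entries(catalog)
  mr <- as.data.table(mouse_records)
  out <- character(0)
  for (g in unique(mr$gene)) {
    sg <- unique(mr$subgroup[mr$gene == g])
    eg <- he[gene == g]
    if (!nrow(eg)) next
    human_sg <- unique(unlist(eg$subgroups))
    if (length(intersect(sg, human_sg))) out <- c(out, g)
  }
  sort(out)
}

#' Tally a gene across the human studies
#'
#' @param catalog a `mutation_catalog`.
#' @param gene human gene symbol (must appear in the catalog).
#' @param lof_letters,missense_letters type-letter sets counted as
#'   loss-of-function (nonsense SNVs / frameshift indels) and missense.
#' @return named numeric vector c(total, lof, missense) summed over human
#'   study entries.
#' @export
tally_gene <- function(catalog, gene, lof_letters = c("N", "F"),
                       missense_letters = "M") {
  if (!gene %in% catalog$genes)
    stop("tally_gene: gene ", gene, " not in catalog")
  he <- human_entries(catalog)
  sel <- he$gene == gene     # computed outside `[` so the argument wins
  eg <- he[sel]
  if (!nrow(eg)) return(c(total = 0, lof = 0, missense = 0))
  sum_letters <- function(types, set) sum(types[names(types) %in% set])
  c(total = sum(eg$total),
    lof = sum(vapply(eg$types, sum_letters, 0, set = lof_letters)),
    missense = sum(vapply(eg$types, sum_letters, 0, set = missense_letters)))
}
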