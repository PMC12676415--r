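# Variant-level colocalization evidence. Two sources flow identically
# downstream: externally produced colocalization tables, and a clearly
# labelled CLPP-style reference approximation (per-variant product of
# per-trait PIPs) computed from the package's own fine-mapping so synthetic
# end-to-end runs need no external tool.

new_coloc_result <- function(trait_set, region_id, vcp, cos, source) {
  structure(list(trait_set = trait_set, region_id = region_id,
                 vcp = vcp, cos = cos, source = source),
            class = "coloc_result")
}

#' Read an externally produced colocalization table
#'
#' Expects a TSV with columns `region_id, cos_id, trait_set, variant_id,
#' vcp` (trait_set comma-separated). Rows with `vcp` outside `[0, 1]` are
#' rejected with a logged reason; the remainder load. An empty file with
#' header yields an empty list.
#'
#' @param path TSV path.
#' @param known_traits Optional character vector; an unknown trait name in
#'   the file raises an error listing the known traits.
#' @return List of `coloc_result` objects with `source = "external"`, one
#'   per `(region_id, trait_set)`, each carrying its colocalized confidence
#'   sets (CoS).
#' @export
read_cos_table <- function(path, known_traits = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("region_id", "cos_id", "trait_set", "variant_id", "vcp")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("CoS table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(tab) == 0) return(list())
  tab$vcp <- as.numeric(tab$vcp)
  bad <- !is.finite(tab$vcp) | tab$vcp < 0 | tab$vcp > 1
  if (any(bad)) {
    message(sum(bad), " CoS row(s) rejected: vcp outside [0, 1]")
    tab <- tab[!bad, , drop = FALSE]
  }
  if (!is.null(known_traits)) {
    seen <- unique(unlist(strsplit(tab$trait_set, ",")))
    unk <- setdiff(seen, known_traits)
    if (length(unk)) {
      stop("unknown trait(s) ", paste(unk, collapse = ", "),
           "; known traits: ", paste(known_traits, collapse = ", "))
    }
  }
  out <- list()
  for (key in unique(paste(tab$region_id, tab$trait_set, sep = "\r"))) {
    sub <- tab[paste(tab$region_id, tab$trait_set, sep = "\r") == key, ,
               drop = FALSE]
    cos <- lapply(split(sub, sub$cos_id), function(s) {
      list(cos_id = s$cos_id[1], variants = s$variant_id,
           vcp = stats::setNames(s$vcp, s$variant_id))
    })
    names(cos) <- NULL
    out[[length(out) + 1]] <- new_coloc_result(
      trait_set = sort(strsplit(sub$trait_set[1], ",")[[1]]),
      region_id = sub$region_id[1],
      vcp = stats::setNames(sub$vcp, sub$variant_id),
      cos = cos, source = "external")
  }
  out
}

#' Write colocalization results in the CoS TSV dialect
#'
#' Emits the same dialect [read_cos_table()] consumes, so external and
#' internally computed results are interchangeable.
#'
#' @param results List of `coloc_result` objects.
#' @param path Output path.
#' @export
write_cos_table <- function(results, path) {
  rows <- list()
  for (res in results) {
    for (cos in res$cos) {
      rows[[length(rows) + 1]] <- data.frame(
        region_id = res$region_id, cos_id = cos$cos_id,
        trait_set = paste(res$trait_set, collapse = ","),
        variant_id = cos$variants, vcp = unname(cos$vcp[cos$variants]),
        source = res$source, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(0), cos_id = character(0),
               trait_set = character(0), variant_id = character(0),
               vcp = numeric(0), source = character(0))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' CLPP-style colocalization from per-trait fine-mapping
#'
#' Reference approximation to multi-trait colocalization: the per-variant
#' colocalization probability is the product of per-trait PIPs
#' (`clpp_v = prod_t pip_t(v)`). Candidate variants are those with
#' `clpp >= clpp_min` that lie in a credible set of every trait; the
#' colocalized confidence set (CoS) is the minimal prefix of candidates (by
#' descending clpp) whose normalized clpp mass reaches `cos_coverage`. An
#' empty candidate set yields no CoS. Outputs are labelled
#' `source = "clpp"` to keep evidence provenance distinct from external
#' colocalization tables.
#'
#' @param fits Named list (by trait) of `susie_fit` objects over the same
#'   variant index, length >= 2.
#' @param clpp_min Candidate threshold on clpp (default 0.01).
#' @param cos_coverage CoS mass level (default 0.95, mirroring the
#'   credible-set convention).
#' @param region_id Region label for the result.
#' @return A `coloc_result` with per-variant `vcp = clpp` and 0 or 1 CoS.
#' @export
clpp_coloc <- function(fits, clpp_min = 0.01, cos_coverage = 0.95,
                       region_id = NA_character_) {
  if (length(fits) < 2) stop("clpp_coloc needs >= 2 traits")
  ids <- fits[[1]]$variant_ids
  for (f in fits[-1]) {
    if (!identical(f$variant_ids, ids)) {
      stop("traits have mismatched variant indices")
    }
  }
  pipmat <- vapply(fits, function(f) unname(f$pip), numeric(length(ids)))
  clpp <- apply(pipmat, 1, prod)
  names(clpp) <- ids
  in_cs <- vapply(fits, function(f) {
    ids %in% unique(unlist(lapply(f$credible_sets, `[[`, "variants")))
  }, logical(length(ids)))
  cand <- which(clpp >= clpp_min & rowSums(in_cs) == length(fits))
  cos <- list()
  if (length(cand)) {
    ord <- cand[order(-clpp[cand], cand)]
    mass <- cumsum(clpp[ord]) / sum(clpp[ord])
    k <- which(mass >= cos_coverage - 1e-9)[1]
    members <- ids[ord[seq_len(k)]]
    cos <- list(list(cos_id = sprintf("%s_cos1", region_id),
                     variants = members, vcp = clpp[members]))
  }
  tr <- names(fits) %||% vapply(fits, `[[`, "", "trait")
  new_coloc_result(trait_set = sort(tr),
                   region_id = region_id %||% fits[[1]]$region_id,
                   vcp = clpp, cos = cos, source = "clpp")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization result [%s] region %s, traits: %s\n",
              x$source, x$region_id, paste(x$trait_set, collapse = ", ")))
  cat(sprintf("  max VCP: %.4f  CoS: %d\n",
              if (length(x$vcp)) max(x$vcp) else 0, length(x$cos)))
  invisible(x)
}
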