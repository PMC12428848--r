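#!/usr/bin/env Rscript
# Cross-(in)compatibility structure of the panel: self-compatible S_C
# carriers, cross-incompatibility groups (identical complete genotypes),
# the full pairwise compatibility matrix, and the documented
# parent-offspring consistency checks. Writes results/compat_matrix.tsv
# and results/incompatibility_groups.csv.

library(SRNaseTyper)
dir.create("results", showWarnings = FALSE)

geno <- load_genotypes()

flags <- self_compatibility_flags(geno)
sc <- flags[flags$flag, ]
cat(sprintf("Self-compatible (S_C) cultivars: %d (%s), all %s\n",
            nrow(sc), paste(sc$cultivar, collapse = ", "),
            paste(unique(sc$area), collapse = "/")))

grp <- incompatibility_groups(geno)
multi <- table(grp$group[!grp$provisional])
multi <- multi[multi > 1]
cat(sprintf("Cross-incompatibility groups with >1 member: %d\n", length(multi)))
for (gid in names(sort(multi, decreasing = TRUE))[1:5]) {
  members <- grp[grp$group == as.integer(gid), ]
  cat(sprintf("  (%s): %s\n", members$genotype[1],
              paste(members$cultivar, collapse = ", ")))
}
write.csv(grp, "results/incompatibility_groups.csv", row.names = FALSE)

m <- compatibility_matrix(geno)
write.table(m, "results/compat_matrix.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
cat(sprintf("Compatibility matrix %dx%d: F=%d S=%d I=%d U=%d cells\n",
            nrow(m), ncol(m), sum(m == "F"), sum(m == "S"),
            sum(m == "I"), sum(m == "U")))

# documented pedigrees: child alleles must come one from each parent
cat("\nParentage consistency checks:\n")
al <- genotype_alleles(geno)
cases <- list(
  list(child = "Jingzaohong", p1 = "Honghebao", p2 = "Dapiantou"),
  list(child = "Jingluofeng", p1 = "Luotuohuang", p2 = NULL)
)
for (cs in cases) {
  res <- check_parentage(al[[cs$child]], al[[cs$p1]],
                         if (!is.null(cs$p2)) al[[cs$p2]])
  cat(sprintf("  %s from %s%s: %s\n", cs$child, cs$p1,
              if (is.null(cs$p2)) " (single parent)" else paste0(" x ", cs$p2),
              if (res$consistent) "consistent" else "INCONSISTENT"))
}
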