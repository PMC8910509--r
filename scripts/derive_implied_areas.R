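#!/usr/bin/env Rscript
# Back-derive per-year land areas from the published valuation table.
#
# Each cell of the valuation table is (area in hm2) x (coefficient in
# yuan/hm2) / 1e9, so dividing any cell by its coefficient recovers the area.
# The largest cell of each class row is used: at 3 printed decimals of
# billions it carries the smallest relative rounding error.
#
# Output: inst/extdata/implied_areas.csv (year, class, function, area_hm2),
# a derived fixture consumed by the test suite and the acceptance script.
# Rerun from the repository root after any edit to the two source CSVs:
#   Rscript scripts/derive_implied_areas.R

coef <- read.csv("inst/extdata/table1_coefficients.csv", check.names = FALSE)
esv  <- read.csv("inst/extdata/table2_esv.csv", check.names = FALSE)

funs <- setdiff(names(coef), "class")
rownames(coef) <- coef$class

rows <- lapply(seq_len(nrow(esv)), function(i) {
  cls <- esv$class[i]
  vals <- unlist(esv[i, funs])
  f <- funs[which.max(vals)]
  data.frame(
    year = esv$year[i], class = cls, fun = f,
    area_hm2 = vals[[f]] * 1e9 / coef[cls, f]
  )
})
out <- do.call(rbind, rows)
names(out)[3] <- "function"
out$area_hm2 <- round(out$area_hm2, 1)

write.csv(out, "inst/extdata/implied_areas.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(out), "rows to inst/extdata/implied_areas.csv\n")

# refresh fixture checksums
files <- c("table1_coefficients.csv", "table2_esv.csv", "pi_coefficients.csv",
           "cnlucc_reclass.csv", "implied_areas.csv")
md5 <- tools::md5sum(file.path("inst/extdata", files))
writeLines(paste(unname(md5), files), "inst/extdata/checksums.md5")
cat("wrote inst/extdata/checksums.md5\n")
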