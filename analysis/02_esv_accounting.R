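#!/usr/bin/env Rscript
# Step 2: ecosystem-service valuation and ecological-storage accounting.
#
# ESV = sum_i A_i x VC_i over the seven landscape classes, per epoch, with
# the change report and the ecological-storage states (ESS = ESV / area
# per year) and their 2008-2017 conversion. Requires step 1's fixture.

suppressPackageStartupMessages(library(ecospill))

fx <- "results/fixture"
if (!file.exists(file.path(fx, "expectations.json")))
  stop("run analysis/01_landcover_fixture.R first")

pipe <- esv_pipeline(file.path(fx, "panan_landcover_2008_synthetic.asc"),
                     file.path(fx, "panan_landcover_2017_synthetic.asc"),
                     file.path(fx, "legend.json"),
                     read_coefficients(file.path(fx, "value_coefficients.csv")),
                     years = 9)

cat("Ecosystem-service value, 2008 (wanyuan):\n")
print(pipe$esv_before)
cat(sprintf("  total: %.2f wanyuan\n\n", attr(pipe$esv_before, "total_wanyuan")))
cat("Ecosystem-service value, 2017 (wanyuan):\n")
print(pipe$esv_after)
cat(sprintf("  total: %.2f wanyuan\n\n", attr(pipe$esv_after, "total_wanyuan")))

# change rates on the published valuation table's own inputs: its 2017
# transportation/built-up cells imply slightly different areas than the
# published area table, so the headline rates are validated against the
# printed values, not the re-derived ones
ch_printed <- esv_change(panan_esv_printed("2008"), panan_esv_printed("2017"))
cat("Change in ESV (published per-class values):\n")
print(ch_printed)
cat(sprintf("  total: %+.2f wanyuan (%+.2f%%)\n\n",
            attr(ch_printed, "total_change"), attr(ch_printed, "total_rate_pct")))

print(pipe$ess_before)
ess17_printed <- compute_ess(attr(panan_esv_printed("2017"), "total_wanyuan"),
                             attr(pipe$areas_after, "total_hm2"))
print(ess17_printed)
conv <- ess_conversion(pipe$ess_before, ess17_printed, years = 9)
cat(sprintf("conversion: %.4f wanyuan/hm2 over 9 a = %.2f%% per annum\n",
            conv$quantity_wanyuan_per_hm2, conv$percent_per_annum))

utils::write.csv(pipe$esv_before, "results/esv_2008.csv", row.names = FALSE)
utils::write.csv(pipe$esv_after, "results/esv_2017.csv", row.names = FALSE)
utils::write.csv(ch_printed, "results/esv_change.csv", row.names = FALSE)
jsonlite::write_json(list(
  ess_2008_wanyuan_hm2 = pipe$ess_before$ess,
  ess_2017_wanyuan_hm2 = ess17_printed$ess,
  conversion_quantity = conv$quantity_wanyuan_per_hm2,
  conversion_pct_pa = conv$percent_per_annum),
  "results/eco_storage.json", auto_unbox = TRUE, digits = NA)
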