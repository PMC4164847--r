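# One-off generator for inst/extdata case files (run from repo root).
for (f in list.files("R", full.names = TRUE)) source(f)

lab3 <- c(C11 = "Natural ecology", C12 = "Ecological protection",
          C13 = "Ecological environment", C21 = "Cost of production",
          C22 = "Production efficiency", C23 = "Input of production",
          C31 = "Forest resources", C32 = "Technological education",
          C33 = "Humanization index")
w3 <- c(C11 = 0.2763, C12 = 0.5954, C13 = 0.1283,
        C21 = 0.3011, C22 = 0.4536, C23 = 0.2453,
        C31 = 0.2392, C32 = 0.4422, C33 = 0.3186)
par3 <- c(C11 = "B1", C12 = "B1", C13 = "B1", C21 = "B2", C22 = "B2",
          C23 = "B2", C31 = "B3", C32 = "B3", C33 = "B3")

leaf <- read.table(header = TRUE, sep = "|", strip.white = TRUE, text = "
id|parent|weight|dir|road|cableway|label
D1|C11|0.0647|positive|0.66|0.78|Integrity of forestry landscape
D2|C11|0.1665|positive|0.73|0.76|Diversity index
D3|C11|0.3310|positive|0.62|0.79|Plantation productivity
D4|C11|0.3310|positive|0.61|0.65|Fertility index
D5|C11|0.1068|positive|0.53|0.82|Stability index
D6|C12|0.2046|positive|0.47|0.58|Water source conservation
D7|C12|0.3403|positive|0.35|0.65|Soil and water conservation
D8|C12|0.2505|positive|0.67|0.71|Air purifying
D9|C12|0.2046|positive|0.36|0.76|Soil improving
D10|C13|0.3309|positive|0.52|0.57|Biomass of forest
D11|C13|0.1794|positive|0.68|0.96|Defending the remaining woods
D12|C13|0.2201|positive|0.45|0.95|Afforestation effect
D13|C13|0.2696|positive|0.89|0.98|Vegetation coverage
D14|C21|0.3106|reverse|0|1|Unit cost for ready (100 million yuan)
D15|C21|0.4361|positive|0|0.29|Saving rate of unit cost
D16|C21|0.2533|reverse|0|1|Pollution controlled cost (100 million yuan)
D17|C22|0.4361|positive|0.56|0.78|Utilization rate of forest resources
D18|C22|0.3106|positive|0.75|0.89|Utilization rate of equipment
D19|C22|0.2533|positive|0.074|0.112|Per capita work efficiency (m3/man)
D20|C23|0.2224|positive|0.30|0.35|Increment of value of annual forest production (10,000 yuan)
D21|C23|0.3357|positive|0.10|0.15|Annual proportion of fixed investment (%)
D22|C23|0.4419|positive|0.40|0.40|Annual proportion of construction investment (%)
D23|C31|0.1793|positive|0.63|0.69|Forestry area (10,000 hm2)
D24|C31|0.2201|positive|0.39|0.44|Unit area amount of growing stock (m3/hm2)
D25|C31|0.2696|positive|0.56|0.66|Forestry land area (10,000 hm2)
D26|C31|0.3310|positive|0.79|0.87|Structural integrity of forestry
D27|C32|0.1376|graded|0.16|0.86|Improvement of scientific level
D28|C32|0.1201|positive|0.15|0.89|Improvement of educational level
D29|C32|0.1049|positive|0.67|0.78|Policies and regulations
D30|C32|0.1614|positive|0.25|0.53|Benefit future generations
D31|C32|0.1260|positive|0.27|0.70|Benefit other industries
D32|C32|0.1026|positive|0.08|0.13|Numbers of professionals
D33|C32|0.0781|positive|0.78|1.00|Ratio of trained staff to entire staff
D34|C32|0.0804|positive|0|0.10|Investment of science and technology project and key laboratory
D35|C32|0.0889|positive|0|0.10|Number of science and technology projects
D36|C33|0.1931|graded|0.35|0.89|Reducing labor intensity
D37|C33|0.3205|positive|0.37|0.90|Advancement of operation and technology
D38|C33|0.2248|positive|0.68|0.76|Operation technical safety
D39|C33|0.2616|positive|0.56|0.86|Harmony of man-machine environment
")

nodes <- list(
  A  = list(label = "Sustainable forest harvesting", children = c("B1", "B2", "B3")),
  B1 = list(label = "Ecological benefits", children = c("C11", "C12", "C13"), weight = 0.5954),
  B2 = list(label = "Economic benefits", children = c("C21", "C22", "C23"), weight = 0.2763),
  B3 = list(label = "Social benefits", children = c("C31", "C32", "C33"), weight = 0.1283)
)
for (id in names(lab3)) {
  nodes[[id]] <- list(label = lab3[[id]],
                      children = leaf$id[leaf$parent == id], weight = w3[[id]])
}
for (k in seq_len(nrow(leaf))) {
  nodes[[leaf$id[k]]] <- list(label = leaf$label[k], direction = leaf$dir[k],
                              weight = leaf$weight[k])
}
h <- build_hierarchy(nodes, c("road", "cableway"))
write_hierarchy(h, "inst/extdata/skidding_hierarchy.yaml")

vals <- rbind(
  data.frame(leaf = leaf$id, alternative = "road", value = leaf$road),
  data.frame(leaf = leaf$id, alternative = "cableway", value = leaf$cableway))
write.csv(vals, "inst/extdata/skidding_values.csv", row.names = FALSE, quote = FALSE)

jd <- rbind(
  data.frame(node = "A", i = c("B1", "B1", "B2"), j = c("B2", "B3", "B3"),
             score = c(1, 1, 1)),
  data.frame(node = "C11",
             i = c("D1", "D1", "D1", "D1", "D2", "D2", "D2", "D3", "D3", "D4"),
             j = c("D2", "D3", "D4", "D5", "D3", "D4", "D5", "D4", "D5", "D5"),
             score = c(0, 0, 0, 0, 0, 0, 1, 0.5, 1, 1)))
write.csv(jd, "inst/extdata/skidding_judgments.csv", row.names = FALSE, quote = FALSE)

costs <- data.frame(
  method = c("road", "cableway"),
  cutting_area_code = "122-1-3",
  working_quantity_ready = c(158.00, 120.00),
  ready_cost = c(16.26, 12.35),
  skidding_quantity_ready = c(1161.20, 747.10),
  skidding_cost = c(119.47, 76.86),
  total_working_quantity = c(1319.2, 867.1),
  fuel_cost = c(7.71, 9.96),
  equipment_depreciation = c(5.00, 5.48),
  day_efficiency_m3_man = c(0.74, 1.12),
  year_efficiency_m3_man = c(185.74, 281.12),
  unit_cost = c(148.44, 104.65))
write.csv(costs, "inst/extdata/skidding_costs.csv", row.names = FALSE, quote = FALSE)
cat("written\n")
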