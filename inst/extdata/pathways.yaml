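# Pathway rulebook for genomic-potential and expression calls.
#
# Members are matched against gene annotations: "EC:<number>" against the EC
# set, "flag:<keyword>" against derived annotation flags, "cazy:<family>"
# against normalized CAZy families.
#
# Thresholds:
#   generic pathways (incl. respiration)  present when >= 60% of members found
#   fermentation end products             present when >= ceil(2/3 * n) members
#                                         found in any one alternative pathway
#   EMP glycolysis                        >= 6 of its 9 members
#   PPP and rare-6C monomer pathways      100% of members ("full pathway")

thresholds:
  generic: 0.60
  emp_min_present: 6
  ppp_fraction: 1.0
  rare_6c_fraction: 1.0
  fermentation_fraction: 0.6666667

pathways:
  EMP:
    category: EMP
    # nine reactions, glucose-6-phosphate isomerase through pyruvate kinase
    members: ["EC:5.3.1.9", "EC:2.7.1.11", "EC:4.1.2.13", "EC:5.3.1.1",
              "EC:1.2.1.12", "EC:2.7.2.3", "EC:5.4.2.11", "EC:4.2.1.11",
              "EC:2.7.1.40"]
  PPP:
    category: PPP
    members: ["EC:1.1.1.49", "EC:3.1.1.31", "EC:1.1.1.44", "EC:5.1.3.1",
              "EC:5.3.1.6", "EC:2.2.1.1", "EC:2.2.1.2"]
  fucose_monomer:
    category: sugar_6C_rare
    members: ["EC:5.3.1.25", "EC:2.7.1.51", "EC:4.1.2.17"]
  mannose_monomer:
    category: sugar_6C_rare
    members: ["EC:5.3.1.8", "EC:2.7.1.7"]
  rhamnose_monomer:
    category: sugar_6C_rare
    members: ["EC:5.3.1.14", "EC:2.7.1.5", "EC:4.1.2.19"]

# Sugar utilization criteria.
#   6C_rare:   full monomer pathway AND >= 6/9 EMP members
#   5C:        specific isomerase AND epimerase AND full PPP
#   6C_common: entry enzyme AND >= 6/9 EMP members (glucose/galactose feed
#              straight into glycolysis; no dedicated monomer pathway)
# `entry` is the isomerase/kinase whose detection (plus one downstream EMP
# member) marks the sugar as expressed; glucose additionally requires one of
# `extra_expressed` because galactose enters the EMP pathway at the same step.
sugars:
  fucose:    {class: 6C_rare, monomer_pathway: fucose_monomer,   entry: "EC:5.3.1.25"}
  mannose:   {class: 6C_rare, monomer_pathway: mannose_monomer,  entry: "EC:5.3.1.8"}
  rhamnose:  {class: 6C_rare, monomer_pathway: rhamnose_monomer, entry: "EC:5.3.1.14"}
  xylose:    {class: 5C, isomerase: "EC:5.3.1.5", epimerase: "EC:5.1.3.1", entry: "EC:5.3.1.5"}
  arabinose: {class: 5C, isomerase: "EC:5.3.1.4", epimerase: "EC:5.1.3.4", entry: "EC:5.3.1.4"}
  glucose:
    class: 6C_common
    entry: "EC:5.3.1.9"
    extra_expressed: ["EC:2.7.1.2", "flag:transporter:glucose"]
  galactose:
    class: 6C_common
    entry: "EC:2.7.1.6"

# Fermentation end products; each product lists alternative pathways and is
# encoded when any one of them passes the two-thirds rule.
fermentation:
  acetate:
    - ["EC:2.3.1.8", "EC:2.7.2.1"]
    - ["EC:6.2.1.1"]
  butyrate:
    - ["EC:2.3.1.9", "EC:1.1.1.157", "EC:4.2.1.55", "EC:1.3.8.1",
       "EC:2.8.3.8", "EC:2.7.2.7"]
  propionate:
    - ["EC:2.8.3.1", "EC:5.4.99.2", "EC:6.4.1.3", "EC:4.1.1.41",
       "EC:1.3.5.4", "EC:4.2.1.2"]
  lactate:
    - ["EC:1.1.1.27"]
  ethanol:
    - ["EC:1.1.1.1", "EC:1.2.1.10"]

# Respiratory electron acceptors; generic 60% rule, reported encoded-only
# (these proteins are not expected in anaerobic-rumen metaproteomes).
respiration:
  fumarate_reduction: ["EC:1.3.5.1", "EC:1.3.5.4"]
  nitrate_reduction:  ["EC:1.7.5.1", "EC:1.9.6.1"]
  nitrite_reduction:  ["EC:1.7.2.2", "EC:1.7.1.15"]
  tmao_reduction:     ["EC:1.7.2.3"]

# Cellulose genomic potential requires a full cellulosome: cohesin AND
# dockerin modules plus at least one cellulase family.
cellulose:
  cellulase_families: [GH48, GH9, GH5]
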