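# Substrate rulebook for SusCD-anchored PULs.
#
# A rule matches a PUL when every `require` group shares at least one family
# with the PUL's normalized CAZy family set (AND across groups, OR within a
# group) and no `forbid` family is present.  Rules are evaluated in priority
# order; the first match wins.  `peptidase_only: true` marks the proteinaceous
# substrate rule: it matches only loci that carry a peptidase and no CAZyme.
#
# No rule may assign the label "cellulose": cellulolytic PULs have never been
# biochemically verified, so beta-1,4-glucan is the most specific glucan call
# made in the absence of side-chain-targeting hydrolases.
rules:
  - substrate: mixed-linked glucan
    priority: 1
    require: [[GH16], [GH30], [GH3]]
  - substrate: beta-1,4-glucan
    priority: 2
    require: [[GH5, GH9], [GH3, GH94]]
    forbid: [GH10, GH11, GH43, GH51, GH67, GH115]
  - substrate: mannan
    priority: 3
    require: [[GH26, GH130], [GH5, GH2, GH36]]
  - substrate: xylan
    priority: 4
    require: [[GH10, GH11], [GH43, GH67, GH115]]
  - substrate: starch
    priority: 5
    require: [[GH13], [GH97, GH31, GH77]]
  - substrate: arabinan
    priority: 6
    require: [[GH43], [GH51]]
  - substrate: pectin
    priority: 7
    require: [[GH28, PL1, GH53]]
  - substrate: protein
    priority: 8
    peptidase_only: true
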