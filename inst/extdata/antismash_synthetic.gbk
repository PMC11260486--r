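LOCUS       synthA            100000 bp    DNA     linear   BCT
DEFINITION  Synthetic antiSMASH-style record for format tests (not a real
            genome).
FEATURES             Location/Qualifiers
     region          1..50000
                     /product="T1PKS"
                     /product="NRPS"
                     /contig_edge="False"
     protocluster    1..45000
                     /aStool="rule-based-clusters"
                     /category="PKS"
                     /product="T1PKS"
                     /protocluster_number="1"
     protocluster    20000..50000
                     /aStool="rule-based-clusters"
                     /category="NRPS"
                     /product="NRPS"
                     /protocluster_number="2"
     protocluster    60001..90000
                     /aStool="rule-based-clusters"
                     /product="terpene"
                     /protocluster_number="3"
ORIGIN
//
LOCUS       synthB             40000 bp    DNA     linear   BCT
DEFINITION  Synthetic antiSMASH-style record for format tests (not a real
            genome).
FEATURES             Location/Qualifiers
     protocluster    complement(101..5000)
                     /aStool="rule-based-clusters"
                     /product="lanthipeptide-class-ii"
                     /protocluster_number="1"
     protocluster    10001..30000
                     /aStool="rule-based-clusters"
                     /product="unusual-novel-type"
                     /protocluster_number="2"
ORIGIN
//
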