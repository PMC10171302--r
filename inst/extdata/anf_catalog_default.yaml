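# Default ANF enzyme catalog: eight antinutritional-factor categories and the
# enzymes whose genes the pipeline screens for. EC numbers are metadata only;
# matching uses product keywords and reference-protein alignment.
#
# PROVENANCE: the reference_proteins sequences below are SYNTHETIC
# representative baits (random sequences, fixed seed; see
# scratch/make_default_catalog.R in the source repository). They are not
# database entries. Replace them with curated family representatives for
# production screens of real genomes.
version: '1.0'
categories:
- category_id: phytate_degradation
  display_name: Phytate degradation (phytase)
  enzymes:
  - enzyme_id: phytase
    name: 3-phytase
    ec_numbers:
    - 3.1.3.8
    - 3.1.3.26
    - 3.1.3.72
    product_keywords:
    - phytase
    - phytate
    reference_proteins:
    - ref_id: phytase_ref1
      sequence: MRYWNHMAYHKKMHEPLMNLWPKELRQFNLQWSWQPIYSCFERDCIEIDNFLTTKQREDGREHQCCHLFYNSGDRSYRDKEQFQVQHICQWSGNMDFQCSIIRMYCWMEHKMNTHKTEYRWMIGCWNGALCLELFLYSQDHGVMTKHVRHYYVVIAEVRDIEQPINGPYEEVMTPFPICCAPGTRQEPAIYDAPTKLHNHPMDIDCYQTYTEYAPGRMEPDTQYKYFDL
    - ref_id: phytase_ref2
      sequence: MKMLTLEGVCKHDNMFCNKFARQHYPCIVCPTQGTAVSTQNVIFCSCEDEHFGIHQVALYYQWHQDNYDDVRNTFSDQPLCIAMGHMCDCKPLVDMQCKWIFWMRRRRYITQTTEIPMGRGSKALCMDACYCSLLKMWVTYMQDASNARFYDPCPISKQDMHKTLKAEYCQQYQAMICVQMKPDGIERSAPDWLCMDINYTIDCPARNDTFLFWGASNLCPVYT
- category_id: myo_inositol
  display_name: Myo-inositol metabolism
  enzymes:
  - enzyme_id: iolG
    name: myo-inositol 2-dehydrogenase
    ec_numbers:
    - 1.1.1.18
    product_keywords:
    - inositol 2-dehydrogenase
    - myo-inositol
    reference_proteins:
    - ref_id: iolG_ref1
      sequence: MFGFLPGFGHGPEYEFPWEYICGIKYSNVGATLQCQMWATYARCVEPAPDCYMHHEFAMHGVMMTEQCPGAEFYRRIYIVPIVGNTTHRIVSSDRVHCKHLRDSNFKCVVTHMEWPHQKMTCYYYKIRLQAVTPIHPFVWLILICLVWNNYLMRVNMKV
  - enzyme_id: suhB
    name: inositol monophosphatase
    ec_numbers:
    - 3.1.3.25
    product_keywords:
    - inositol monophosphatase
    reference_proteins:
    - ref_id: suhB_ref1
      sequence: MYCPMDEWKSYQNHRDSRIYYTTWMACKDQHEYDYTAETNAVVSLTCQETDNQFFICCGKALAQSKLTLRFPEPVNIGMFATLDQEHDPFMVSVVHINEHHLQIRLMYEMLLWSIMRAQLYDPTAIQWLRLEMEFAEKWRYWIVVPRKVRHDYKFKEIQRLCYGQQ
- category_id: tannin_degradation
  display_name: Tannin degradation (tannase)
  enzymes:
  - enzyme_id: tanA
    name: tannase
    ec_numbers:
    - 3.1.1.20
    product_keywords:
    - tannase
    - tannin acyl hydrolase
    reference_proteins:
    - ref_id: tanA_ref1
      sequence: MALDDKMIMRPHSPEQTLQDTIQAHPVNCSGWMCPIDCMIQWGKFRVENRWAGFLITELWSANNVSCWKEVDPNGHPIVPDMTFFAPMGPCECCFFYLFCDLWVAFSNFPKICHEDNGVYGFDQNGVYIPAIIAAETSKSSLSTIIQSQVDTINEPLQGFMVWIVCIIMEATQEPPPFQIVAHTFSFTILFDTDGHIKTLTMSIFC
- category_id: phenolic_compound
  display_name: Phenolic compound metabolism
  enzymes:
  - enzyme_id: pad
    name: phenolic acid decarboxylase
    ec_numbers:
    - 4.1.1.102
    product_keywords:
    - phenolic acid decarboxylase
    reference_proteins:
    - ref_id: pad_ref1
      sequence: MHMCNDVAAERREALSPNPWTWFMSICQTCNYHHRRQGIEWYCSITLTMDGFLHFCRWEVVKFFQKCVPSMQQSQIEQWQNHLTHPFTFSLNQWSCRGEVWGIRNMHSEWQKGHSVRGENTHDWCYEARMQQFFMKACESPVNQHNLCFR
  - enzyme_id: ubiX
    name: 3-polyprenyl-4-hydroxybenzoate carboxy-lyase UbiX
    ec_numbers:
    - 2.5.1.129
    product_keywords:
    - polyprenyl-4-hydroxybenzoate carboxy-lyase
    - flavin prenyltransferase
    - ubix
    reference_proteins:
    - ref_id: ubiX_ref1
      sequence: MPMGPYVGTFHTQWQAKISTWDARWVTTAVFWWGNFMPYWGCDLTDQKVYCGWHELRAHRTDQMLPMVSSQTHTVYIWSGTDQEYMTDHWPGRFVIKATLVGADLCVEWELCQHFNSGQMMFENKMGHVEMLAPRVTGMDAIMSWKVSHED
- category_id: lectin_binding
  display_name: Lectin
  enzymes:
  - enzyme_id: lec
    name: lectin
    ec_numbers: []
    product_keywords:
    - lectin
    reference_proteins:
    - ref_id: lec_ref1
      sequence: MLRAIIMETTDDMKKLMIVKKNSAHMKETDHQCTNFPTALVKPQPVETATADRTQNADHFNIRCMMCYSRCCNAKYELISMRIQVAEKAKIKSDMLTHDWCPNGNQNQLDPTWHNSIHAAACFNSIEKGLFRKFYFYFASCWEVAYYQGWGHYEMNMWERTKYRCMKDKDDNEGCHQTAFFGKWRMTDNSYQCYQKITKIWNCAVYLMLGMASAWTPSGAWDSHSWK
- category_id: trypsin_protease
  display_name: Trypsin / trypsin-like protease
  enzymes:
  - enzyme_id: tlp
    name: trypsin-like serine protease
    ec_numbers:
    - 3.4.21.4
    product_keywords:
    - trypsin
    reference_proteins:
    - ref_id: tlp_ref1
      sequence: MRMCMYEQYPNQMPVCQGKPSGLSHTVQSWGIAYFPWFVITMQMIAARIDDVYVDVPCLQWTAYDTAYSRYYRKLNFFYECPDYYDTIRETLVQTEIMRYLRNMRGNKFVEKQNENMYCKYHHQPCIGKCCPEQGCFVCKMWYEPPKFYCFFIMLQMFTIRPIARGAQRKKKSWWPEWQNAQLFYTCFTIENVNHHWSAHFGVQGEADHTHGFFDQAWYGCLGASQQMMCYGYPAPCRN
- category_id: saponin_degradation
  display_name: Saponin degradation (beta-glucuronidase)
  enzymes:
  - enzyme_id: gus
    name: beta-glucuronidase
    ec_numbers:
    - 3.2.1.31
    product_keywords:
    - glucuronidase
    reference_proteins:
    - ref_id: gus_ref1
      sequence: MVWMVCRPNSVSILIKEGNCVLQMAAQNLNLLTGDFNWTIEVGIMDLCCHICLSDRKLHSFFFRFMVHLGHNREYTLPADHIDSHWRNSYFEANDQHACINYTGYRALDDVYYSWVSLTRRQQSWMLP
- category_id: alpha_gos
  display_name: alpha-GOS degradation (alpha-galactosidase)
  enzymes:
  - enzyme_id: aga
    name: alpha-galactosidase
    ec_numbers:
    - 3.2.1.22
    product_keywords:
    - alpha-galactosidase
    - melibiase
    reference_proteins:
    - ref_id: aga_ref1
      sequence: MVFTMSWQKSNIRVWDNKMIVVWAEPPDTHNSWNAHTQGEDYHCLKVVMRFKCWKFRYEEKPGSNSGWEMFQREPKANQFVSKFRVYRKVWSATVVSDRNILASWWIRVHWPAFAWDLESYVEDTQGLGWYNWRFMLHDQWRPSSCPGGNRQQVMTGMPYGWLIMYMYWMPTNCGPCMQMRYQFKMQCNVGPIW
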