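# Default SCFA / lactate pathway rules for the human gut microbiome
# reference collection.
#
# Grammar: a pathway variant is an AND over role groups; a role group is an
# OR over alternatives (non-orthologous gene displacements); an alternative
# is a single functional role or a co-required role combination (written as
# a nested list).  Shared segments are defined once per product and
# referenced by variants, so e.g. the universal crotonyl-CoA -> butyryl-CoA
# step is a first-class named entity.
catalogue:
  # -- butyrate synthesis -------------------------------------------------
  - {role: Thl,       ec: "2.3.1.9",   description: "acetyl-CoA acetyltransferase (thiolase)"}
  - {role: Hbd,       ec: "1.1.1.157", description: "3-hydroxybutyryl-CoA dehydrogenase"}
  - {role: Crt,       ec: "4.2.1.55",  description: "3-hydroxybutyryl-CoA dehydratase (crotonase)"}
  - {role: AldD,      ec: "1.2.1.76",  description: "CoA-dependent succinate-semialdehyde dehydrogenase"}
  - {role: AbfH,      ec: "1.1.1.61",  description: "NAD-dependent 4-hydroxybutyrate dehydrogenase"}
  - {role: Cat,       ec: "2.8.3.-",   description: "4-hydroxybutyrate CoA-transferase"}
  - {role: AbfD,      ec: "4.2.1.120", description: "4-hydroxybutyryl-CoA dehydratase"}
  - {role: GctAB,     ec: "2.8.3.12",  description: "glutaconate CoA-transferase"}
  - {role: HgdABC,    ec: "4.2.1.-",   description: "2-hydroxyglutaryl-CoA dehydratase"}
  - {role: GcdABC,    ec: "4.1.1.70",  description: "glutaconyl-CoA decarboxylase"}
  - {role: KamA,      ec: "5.4.3.2",   description: "lysine 2,3-aminomutase"}
  - {role: KamDE,     ec: "5.4.3.3",   description: "beta-lysine 5,6-aminomutase"}
  - {role: KDD,       ec: "1.4.1.11",  description: "3,5-diaminohexanoate dehydrogenase"}
  - {role: KCE,       ec: "2.3.1.-",   description: "3-keto-5-aminohexanoate cleavage enzyme"}
  - {role: KAL,       ec: "4.3.1.14",  description: "3-aminobutyryl-CoA ammonia lyase"}
  - {role: Bcd-EtfAB, ec: "1.3.8.1",   description: "butyryl-CoA dehydrogenase electron-transferring flavoprotein complex"}
  - {role: But,       ec: "2.8.3.9",   description: "butyryl-CoA:acetate CoA-transferase"}
  - {role: CtfAB,     ec: "2.8.3.8",   description: "butyryl-CoA transferase (two-subunit)"}
  - {role: Ptb,       ec: "2.3.1.19",  description: "phosphate butyryltransferase"}
  - {role: Buk,       ec: "2.7.2.7",   description: "butyrate kinase"}
  # -- propionate synthesis ----------------------------------------------
  - {role: PST,       ec: "2.8.3.-",   description: "succinate:propionyl-CoA transferase"}
  - {role: AarC,      ec: "2.8.3.18",  description: "succinyl-CoA:acetate CoA-transferase (alternative CoA-transferase)"}
  - {role: MutAB,     ec: "5.4.99.2",  description: "methylmalonyl-CoA mutase, fused catalytic/B12-binding subunits"}
  - {role: MutA2,     ec: "5.4.99.2",  description: "methylmalonyl-CoA mutase, catalytic subunit (two-subunit form)"}
  - {role: MutC,      ec: "5.4.99.2",  description: "methylmalonyl-CoA mutase, B12-binding subunit (two-subunit form)"}
  - {role: MutB2,     ec: "",          description: "accessory GTPase of the two-subunit methylmalonyl-CoA mutase (annotation only, never required)"}
  - {role: Mce,       ec: "5.1.99.1",  description: "methylmalonyl-CoA epimerase"}
  - {role: MmdABCDE,  ec: "4.1.1.41",  description: "methylmalonyl-CoA decarboxylase, multisubunit complex"}
  - {role: Mmd,       ec: "4.1.1.41",  description: "methylmalonyl-CoA decarboxylase, single-subunit form"}
  - {role: MMCT,      ec: "2.1.3.1",   description: "methylmalonyl-CoA carboxyltransferase (transcarboxylase, 5S/12S)"}
  - {role: Pct,       ec: "2.8.3.1",   description: "propionate CoA-transferase"}
  - {role: LcdABC,    ec: "4.2.1.54",  description: "lactoyl-CoA dehydratase, three-subunit"}
  - {role: LcdX,      ec: "4.2.1.54",  description: "lactoyl-CoA dehydratase, crotonase-family form"}
  - {role: Acr,       ec: "1.3.1.-",   description: "acryloyl-CoA reductase"}
  - {role: PduCDE,    ec: "4.2.1.28",  description: "B12-dependent propanediol dehydratase"}
  - {role: PduC2,     ec: "4.2.1.28",  description: "B12-independent propanediol dehydratase (glycyl radical enzyme)"}
  - {role: PduD2,     ec: "",          description: "PduC2 activating enzyme, radical SAM family"}
  - {role: PduP,      ec: "1.2.1.87",  description: "propionaldehyde dehydrogenase"}
  - {role: PduL,      ec: "2.3.1.222", description: "phosphate propanoyltransferase"}
  - {role: PduW,      ec: "2.7.2.15",  description: "propionate kinase"}
  # -- acetate, formate, lactate -----------------------------------------
  - {role: Pta,       ec: "2.3.1.8",   description: "phosphate acetyltransferase"}
  - {role: AckA,      ec: "2.7.2.1",   description: "acetate kinase"}
  - {role: PflB,      ec: "2.3.1.54",  description: "pyruvate formate-lyase"}
  - {role: PflA,      ec: "1.97.1.4",  description: "pyruvate formate-lyase activating enzyme"}
  - {role: L-LDH,     ec: "1.1.1.27",  description: "L-lactate dehydrogenase"}
  - {role: D-LDH,     ec: "1.1.1.28",  description: "D-lactate dehydrogenase"}

pathways:
  butyrate:
    shared:
      universal:
        groups:
          - Bcd-EtfAB
      terminal:
        groups:
          - alternatives:
              - But
              - CtfAB
              - [Ptb, Buk]
    variants:
      P1:           # acetyl-CoA route
        groups: [Thl, Hbd, Crt]
        shared: [universal, terminal]
      P2:           # succinate route
        groups: [AldD, AbfH, Cat, AbfD]
        shared: [universal, terminal]
      P3:           # glutamate route
        groups: [GctAB, HgdABC, GcdABC]
        shared: [universal, terminal]
      P4:           # lysine route
        groups: [KamA, KamDE, KDD, KCE, KAL]
        shared: [universal, terminal]
  propionate:
    variants:
      P1:           # succinate route
        groups:
          - alternatives: [PST, AarC]
            relaxable: true
          - alternatives:
              - MutAB
              - [MutA2, MutC]
          - Mce
          - alternatives: [MmdABCDE, Mmd, MMCT]
      P2:           # lactate (acrylate) route
        groups:
          - Pct
          - alternatives: [LcdABC, LcdX]
          - Acr
      P3:           # propanediol route
        groups:
          - alternatives:
              - PduCDE
              - [PduC2, PduD2]
          - PduP
          - PduL
          - PduW
        sublabel:
          label: "P3*"
          when_only: [PduC2, PduD2]
  acetate:
    variants:
      A:
        groups: [Pta, AckA]
  formate:
    variants:
      F:
        groups: [PflB, PflA]
  L-lactate:
    variants:
      L:
        groups: [L-LDH]
  D-lactate:
    variants:
      D:
        groups: [D-LDH]
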