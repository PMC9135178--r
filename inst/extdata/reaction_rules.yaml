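# Enzyme-free biotransformation rules, one record per rule.
# Fields: rule_id, name, category (one of the eight functional-group labels),
# reaction_smarts (single-reactant transform), notes (optional).
# This is a curated representative set covering all eight categories; larger
# rule collections in the same schema load through load_ruleset().
- rule_id: est01
  name: Carboxylic ester hydrolysis
  category: esters
  reaction_smarts: "[#6:1][CX3:2](=[O:3])[OX2:4][#6:5]>>[#6:1][C:2](=[O:3])[O:4].[O][#6:5]"
  notes: Gastric/esterase-type cleavage to acid plus alcohol; also opens lactones.
- rule_id: est02
  name: Sulfate ester hydrolysis
  category: esters
  reaction_smarts: "[#6:1][OX2:2]S(=O)(=O)[OX2;H1]>>[#6:1][O:2]"
  notes: Releases the parent alcohol or phenol from its sulfate conjugate.
- rule_id: eth01
  name: Ether / glycosidic C-O cleavage
  category: ethers
  reaction_smarts: "[CX4,c:1][OX2:2][CX4;!H3:3]>>[CX4,c:1][O:2].[O][CX4:3]"
  notes: Deglycosylation and general ether scission; dominant for microbiota-mediated aglycone release.
- rule_id: eth02
  name: O-demethylation
  category: ethers
  reaction_smarts: "[c:1][OX2:2][CH3]>>[c:1][O:2]"
  notes: Aryl methyl ether to phenol; the methyl leaves as a one-carbon unit.
- rule_id: aro01
  name: Aromatic hydroxylation
  category: aromatics
  reaction_smarts: "[cH:1]>>[c:1]O"
  notes: Arene oxidation to phenol at any unsubstituted ring position.
- rule_id: aro02
  name: Aromatic dehydroxylation
  category: aromatics
  reaction_smarts: "[c:1][OX2;H1]>>[c:1]"
  notes: Reductive removal of a phenolic hydroxyl.
- rule_id: ami01
  name: N-demethylation
  category: amines
  reaction_smarts: "[NX3:1][CH3]>>[N:1]"
  notes: Loss of an N-methyl group.
- rule_id: ami02
  name: N-acetylation
  category: amines
  reaction_smarts: "[NX3;H2:1]>>[N:1]C(C)=O"
  notes: Conjugative acetylation of a primary amine.
- rule_id: alk01
  name: Aliphatic hydroxylation
  category: alkanes
  reaction_smarts: "[CX4;!H0:1]>>[C:1]O"
  notes: C-H oxidation at any sp3 carbon bearing hydrogen.
- rule_id: alk02
  name: Dehydrogenation
  category: alkanes
  reaction_smarts: "[CX4;!H0:1][CX4;!H0:2]>>[C:1]=[C:2]"
  notes: Two adjacent sp3 C-H centers lose hydrogen to form an alkene.
- rule_id: ene01
  name: Alkene reduction
  category: alkenes
  reaction_smarts: "[C:1]=[C:2]>>[C:1][C:2]"
  notes: Hydrogenation of a non-aromatic carbon-carbon double bond.
- rule_id: ene02
  name: Alkene hydration
  category: alkenes
  reaction_smarts: "[C:1]=[C:2]>>[C:1][C:2]O"
  notes: Water addition across the double bond; both regiochemistries arise from the two template orientations.
- rule_id: alc01
  name: Primary alcohol oxidation
  category: alcohols
  reaction_smarts: "[CX4;H2:1][OX2;H1:2]>>[C:1](=[O:2])O"
  notes: Oxidation through the aldehyde to the carboxylic acid.
- rule_id: alc02
  name: Secondary alcohol oxidation
  category: alcohols
  reaction_smarts: "[CX4;H1:1][OX2;H1:2]>>[C:1]=[O:2]"
  notes: Oxidation to the ketone.
- rule_id: oth01
  name: Ketone reduction
  category: others
  reaction_smarts: "[#6:1][CX3:2](=[O:3])[#6:4]>>[#6:1][C:2]([O:3])[#6:4]"
  notes: Carbonyl reduction to the secondary alcohol.
- rule_id: oth02
  name: Decarboxylation
  category: others
  reaction_smarts: "[#6:1][CX3](=O)[OX2;H1]>>[#6:1]"
  notes: Loss of a carboxyl group as CO2.
- rule_id: oth03
  name: Amide hydrolysis
  category: others
  reaction_smarts: "[#6:1][CX3:2](=[O:3])[NX3:4]>>[#6:1][C:2](=[O:3])O.[N:4]"
  notes: Cleavage to the carboxylic acid and the amine.
- rule_id: oth04
  name: Aldehyde reduction
  category: others
  reaction_smarts: "[CX3;H1:1]=[O:2]>>[C:1][O:2]"
  notes: Reduction of an aldehyde to the primary alcohol.
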