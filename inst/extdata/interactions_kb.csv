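"drug_a","drug_b","mechanism","action","documentation","severity","description"
"haloperidol","citalopram","pharmacodynamic","avoid","theoretical","severe","QT-prolongation"
"levomepromazine","haloperidol","pharmacodynamic","avoid","theoretical","severe","QT-prolongation"
"citalopram","risperidone","pharmacodynamic","informative","case","severe","Priapism/QT-prolongation"
"citalopram","levomepromazine","pharmacodynamic","informative","theoretical","severe","QT-prolongation"
"citalopram","zopiclone","pharmacodynamic","informative","theoretical","moderate","Sedation"
"zopiclone","carbamazepine","pharmacodynamic","informative","theoretical","mild","Sedation"
"carbamazepine","olanzapine","pharmacokinetic","adjust dose","study","moderate","Olanzapine exposure reduced"
"carbamazepine","risperidone","pharmacokinetic","monitor","study","moderate","Risperidone exposure reduced"
"carbamazepine","nortriptyline","pharmacokinetic","monitor","study","moderate","Nortriptyline exposure reduced"
"valproic acid","carbamazepine","pharmacokinetic","adjust dose","extensive","moderate","Carbamazepine-epoxide increased"
"mirtazapine","oxazepam","pharmacodynamic","monitor","theoretical","moderate","Sedation"
"mirtazapine","diazepam","pharmacodynamic","monitor","study","moderate","CNS depression"
"mirtazapine","olanzapine","pharmacodynamic","monitor","case","moderate","Sedation"
"mirtazapine","escitalopram","pharmacodynamic","monitor","theoretical","severe","Serotonin syndrome"
"escitalopram","oxazepam","pharmacodynamic","informative","theoretical","moderate","Sedation"
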