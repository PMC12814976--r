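{
"acetic-acid": [],
"acetone": [],
"benzene": [],
"cyclohexane": [],
"dimethyl-ether": [],
"ethane": [],
"ethanol": [],
"ethene": [],
"ethyne": [],
"fluorobenzene": [],
"methane": [],
"methanethiol": [],
"methyl-phenyl-ether": [
"1-7"
],
"methylamine": [],
"n-methylacetamide": [
"2-4"
],
"phenol": [],
"propane": [],
"pyridine": [],
"rand1": [
"1-4"
],
"rand10": [
"14-16",
"5-7",
"8-12"
],
"rand11": [
"1-9"
],
"rand12": [
"1-3"
],
"rand13": [
"10-17",
"13-21",
"6-8",
"8-14"
],
"rand14": [],
"rand15": [],
"rand16": [
"6-7"
],
"rand17": [],
"rand18": [],
"rand19": [],
"rand2": [],
"rand20": [],
"rand21": [],
"rand22": [],
"rand23": [],
"rand24": [
"2-3",
"2-8"
],
"rand25": [],
"rand26": [
"11-14",
"4-7",
"7-9",
"9-11"
],
"rand27": [
"1-9"
],
"rand28": [
"1-7"
],
"rand29": [
"3-8"
],
"rand3": [],
"rand30": [
"3-4"
],
"rand31": [],
"rand32": [],
"rand33": [],
"rand34": [],
"rand35": [
"1-9",
"6-15"
],
"rand36": [],
"rand37": [],
"rand38": [],
"rand39": [],
"rand4": [
"10-17",
"3-11"
],
"rand40": [
"1-3"
],
"rand5": [],
"rand6": [],
"rand7": [
"2-4"
],
"rand8": [],
"rand9": [
"4-8",
"5-12"
],
"toluene": []
}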