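{"item_id":"demo-001","stem":"A 54-year-old man presents with crushing chest pain radiating to the left arm. Which is the most appropriate initial investigation?","options":{"A":"Electrocardiogram","B":"Chest radiograph","C":"D-dimer","D":"Echocardiogram"},"gold":"A","dataset_tag":"demo","language_tag":"en"}
{"item_id":"demo-002","stem":"Which vitamin deficiency causes scurvy?","options":{"A":"Vitamin A","B":"Vitamin B12","C":"Vitamin C","D":"Vitamin D"},"gold":"C","dataset_tag":"demo","language_tag":"en"}
{"item_id":"demo-003","stem":"First-line pharmacotherapy for uncomplicated essential hypertension in a 48-year-old includes which class?","options":{"A":"Alpha blockers","B":"Thiazide diuretics","C":"Nitrates","D":"Loop diuretics"},"gold":"B","dataset_tag":"demo","language_tag":"en"}
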