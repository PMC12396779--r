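{"item_id":"demo-001","model_tag":"demo-model","prompt_variant":"vanilla","temperature":0,"raw_text":"The correct answer is: A. My confidence level is: 95.","token_steps":[{"token":"The","top_k":[["The",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" correct","top_k":[[" correct",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" answer","top_k":[[" answer",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" A","top_k":[[" A",-0.0725706928348354],[" B",-3.2188758248682],[" C",-3.91202300542815],[" D",-4.60517018598809]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" My","top_k":[[" My",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" confidence","top_k":[[" confidence",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" level","top_k":[[" level",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" 95","top_k":[[" 95",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]}]}
{"item_id":"demo-002","model_tag":"demo-model","prompt_variant":"vanilla","temperature":0,"raw_text":"The correct answer is: C. My confidence level is: 95.","token_steps":[{"token":"The","top_k":[["The",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" correct","top_k":[[" correct",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" answer","top_k":[[" answer",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" C","top_k":[[" C",-0.0304592074847086],[" A",-3.91202300542815],[" B",-5.29831736654804],[" D",-5.29831736654804]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" My","top_k":[[" My",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" confidence","top_k":[[" confidence",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" level","top_k":[[" level",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" 95","top_k":[[" 95",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]}]}
{"item_id":"demo-003","model_tag":"demo-model","prompt_variant":"vanilla","temperature":0,"raw_text":"The correct answer is: D. My confidence level is: 90.","token_steps":[{"token":"The","top_k":[["The",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" correct","top_k":[[" correct",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" answer","top_k":[[" answer",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" D","top_k":[[" D",-0.967584026261706],[" B",-1.10866262452161],[" A",-1.77195684193188],[" C",-2.12026353620009]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" My","top_k":[[" My",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" confidence","top_k":[[" confidence",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" level","top_k":[[" level",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" is","top_k":[[" is",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":":","top_k":[[":",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":" 90","top_k":[[" 90",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]},{"token":".","top_k":[[".",0],["<pad1>",-31],["<pad2>",-32],["<pad3>",-33]]}]}
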