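{
  "today": {"year": 2019, "month": 5, "day": 10},
  "pictures": [
    ["elephant"],
    ["wheelbarrow", "barrow", "wheel barrow"]
  ],
  "q3_abstract": ["measuring instruments", "measuring tools", "instruments", "tools for measuring"],
  "q3_concrete": ["both have numbers", "numbers", "both are long", "made of metal"],
  "q4": {"bill": 20, "amount": 13.45},
  "q5": {"sum": 2.25, "denomination": 0.25},
  "memory_phrases": ["Have you finished?", "Are you done?"],
  "dictionaries": {
    "animals": ["dog", "cat", "horse", "cow", "sheep", "goat", "pig", "rabbit",
                "lion", "tiger", "bear", "wolf", "fox", "deer", "moose", "elk",
                "mouse", "rat", "squirrel", "hedgehog", "eagle", "owl", "duck",
                "goose", "chicken", "swan", "stork", "frog", "snake", "lizard",
                "fish", "shark", "whale", "dolphin", "seal", "otter", "beaver",
                "badger", "lynx", "elephant", "giraffe", "zebra", "camel", "monkey"],
    "fruits_vegetables": ["apple", "pear", "plum", "cherry", "strawberry",
                "raspberry", "blueberry", "grape", "orange", "lemon", "banana",
                "peach", "apricot", "melon", "watermelon", "carrot", "potato",
                "tomato", "cucumber", "onion", "garlic", "cabbage", "beet",
                "pumpkin", "pepper", "pea", "bean", "lettuce", "spinach", "radish"],
    "kitchen": ["spoon", "fork", "knife", "plate", "bowl", "cup", "mug", "pot",
                "pan", "kettle", "oven", "stove", "fridge", "freezer", "sink",
                "table", "chair", "glass", "jug", "tray", "grater", "whisk",
                "ladle", "colander", "cutting board", "toaster", "mixer", "scale"],
    "countries": ["lithuania", "latvia", "estonia", "poland", "germany",
                "france", "spain", "italy", "portugal", "sweden", "norway",
                "finland", "denmark", "netherlands", "belgium", "austria",
                "switzerland", "greece", "ireland", "iceland", "canada",
                "brazil", "argentina", "japan", "china", "india", "australia",
                "egypt", "kenya", "mexico"]
  }
}
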