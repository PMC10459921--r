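{
  "images": [
    {
      "id": 1,
      "width": 256,
      "height": 256,
      "file_name": "tile_001.ppm"
    }
  ],
  "annotations": [
    {
      "id": 1,
      "image_id": 1,
      "category_id": 1,
      "bbox": [10.5, 20, 24, 24],
      "area": 576,
      "iscrowd": 0
    },
    {
      "id": 2,
      "image_id": 1,
      "category_id": 1,
      "bbox": [100, 50.75, 30, 28],
      "area": 840,
      "iscrowd": 0
    },
    {
      "id": 3,
      "image_id": 1,
      "category_id": 1,
      "bbox": [200.25, 30, 18.5, 18.5],
      "area": 342.25,
      "iscrowd": 0
    }
  ],
  "categories": [
    {
      "id": 1,
      "name": "wbc"
    }
  ]
}
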